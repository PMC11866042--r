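# Slide-level quality control.
#
# Three axes, mirroring what makes reticulin preparations fragile in
# practice: (1) stain-colour variation across a cohort, measured on each
# slide's dominant tissue colour in both RGB and CIELAB; (2) preservation
# of bone area (decalcified trabeculae detach easily during restaining);
# (3) the count of analysable intertrabecular tiles that survive the
# fat/bone composition filter.

#' Dominant tissue colour of a slide
#'
#' Tissue pixels are quantised to a 16-level-per-channel cube; the modal
#' bin is found (ties broken towards the lowest bin index) and the mean of
#' the actual pixels in that bin is returned, so a uniformly coloured
#' region yields its exact colour.
#'
#' @param image 8-bit RGB array.
#' @param tissue_mask Logical matrix selecting tissue pixels.
#' @return Named numeric triple `(r, g, b)` in 0-255.
#' @export
dominant_colour <- function(image, tissue_mask) {
  assert_image(image); assert_mask(tissue_mask, "tissue_mask")
  idx <- which(tissue_mask)
  if (length(idx) == 0) abort("tissue mask is empty")
  n <- prod(dim(tissue_mask))
  r <- image[idx]; g <- image[idx + n]; b <- image[idx + 2 * n]
  bin <- (clamp(r, 0, 255) %/% 16) * 256 + (clamp(g, 0, 255) %/% 16) * 16 +
    clamp(b, 0, 255) %/% 16
  counts <- table(bin)
  modal <- as.numeric(names(counts)[which.max(counts)])  # which.max: first = lowest bin
  inbin <- bin == modal
  c(r = mean(r[inbin]), g = mean(g[inbin]), b = mean(b[inbin]))
}

#' Convert 8-bit sRGB colours to CIELAB
#'
#' Standard pipeline: sRGB transfer linearisation, the sRGB/D65 matrix to
#' XYZ, then the CIE L*a*b* piecewise cube-root transform against the
#' D65/2-degree white point. Vectorised over rows.
#'
#' @param rgb Length-3 vector or n x 3 matrix of 8-bit values (0-255).
#' @return Length-3 vector or n x 3 matrix of `(L, a, b)`; L* in
#'   \[0, 100\].
#' @export
rgb_to_cielab <- function(rgb) {
  single <- is.null(dim(rgb))
  m <- if (single) matrix(rgb, 1, 3) else as.matrix(rgb)[, 1:3, drop = FALSE]
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  # sRGB D65 linear RGB -> XYZ
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wp <- c(0.95047, 1.00000, 1.08883)  # D65/2
  xr <- sweep(xyz, 2, wp, "/")
  eps <- 216 / 24389; kappa <- 24389 / 27
  f <- ifelse(xr > eps, xr^(1 / 3), (kappa * xr + 16) / 116)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  out <- cbind(L = L, a = a, b = b)
  if (single) out[1, ] else out
}

#' Cohort stain-colour variation and arm comparison
#'
#' Given one dominant colour per slide with an arm label (e.g. reticulin
#' vs H&E), computes per-channel variances and the total dispersion (trace
#' of the covariance matrix) in both RGB and CIELAB, and compares arm
#' dispersions by a seeded bootstrap of the trace ratio. The comparison is
#' a pragmatic dispersion test, not a claim about which test produced any
#' published p-value.
#'
#' @param colours Data frame with columns `arm` and `r`, `g`, `b`
#'   (dominant colours, 0-255).
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level for the ratio interval.
#' @return List with `by_channel` (tibble of per-arm, per-space, per
#'   channel variances), `dispersion` (per-arm trace per space) and
#'   `comparison` (trace ratio arm1/arm2 per space with bootstrap CI and
#'   the fraction of resamples with ratio <= 1).
#' @export
colour_variation <- function(colours, n_boot = 500L, seed = 1L,
                             conf_level = 0.95) {
  stopifnot(all(c("arm", "r", "g", "b") %in% names(colours)))
  arms <- unique(colours$arm)
  if (any(table(colours$arm) < 2)) abort("need >= 2 slides per arm")
  lab <- rgb_to_cielab(as.matrix(colours[, c("r", "g", "b")]))
  dat <- dplyr::bind_cols(as_tibble(colours),
                          tibble(L = lab[, 1], a = lab[, 2], b2 = lab[, 3]))
  chans <- list(RGB = c("r", "g", "b"), LAB = c("L", "a", "b2"))
  by_channel <- purrr::imap(chans, function(cc, space) {
    dat |> group_by(.data$arm) |>
      summarise(dplyr::across(dplyr::all_of(cc), var), .groups = "drop") |>
      tidyr::pivot_longer(-"arm", names_to = "channel", values_to = "variance") |>
      mutate(space = space)
  }) |> bind_rows()
  dispersion <- by_channel |> group_by(.data$arm, .data$space) |>
    summarise(trace = sum(.data$variance), .groups = "drop")
  comparison <- NULL
  if (length(arms) == 2) {
    a1 <- arms[1]; a2 <- arms[2]
    tr <- function(df, cc) sum(apply(df[, cc], 2, var))
    comparison <- with_seed(seed, purrr::imap(chans, function(cc, space) {
      d1 <- dat[dat$arm == a1, ]; d2 <- dat[dat$arm == a2, ]
      obs <- tr(d1, cc) / tr(d2, cc)
      boot <- replicate(n_boot, {
        tr(d1[sample.int(nrow(d1), replace = TRUE), ], cc) /
          tr(d2[sample.int(nrow(d2), replace = TRUE), ], cc)
      })
      boot <- boot[is.finite(boot)]
      al <- (1 - conf_level) / 2
      tibble(space = space, arm_ratio = paste(a1, "/", a2),
             trace_ratio = obs,
             ci_lo = if (length(boot)) quantile(boot, al, names = FALSE) else NA_real_,
             ci_hi = if (length(boot)) quantile(boot, 1 - al, names = FALSE) else NA_real_,
             p_le_1 = if (length(boot)) mean(boot <= 1) else NA_real_)
    }) |> bind_rows())
  }
  list(by_channel = by_channel, dispersion = dispersion,
       comparison = comparison)
}

#' Bone area in square millimetres
#'
#' @param bone_mask Logical matrix of bone pixels.
#' @param mpp Microns per pixel (> 0).
#' @return Area in mm^2: `pixel count * (mpp / 1000)^2`.
#' @export
bone_area <- function(bone_mask, mpp) {
  assert_mask(bone_mask, "bone_mask")
  if (mpp <= 0) abort("`mpp` must be > 0")
  sum(bone_mask) * (mpp / 1000)^2
}

#' Count analysable tiles, optionally within an annotation
#'
#' @param table A `tile_table` with the `analysable` flag populated.
#' @param annotation_mask Optional logical matrix; a tile counts only if
#'   its centre pixel lies inside the annotation.
#' @return Non-negative integer count.
#' @export
analysable_tile_count <- function(table, annotation_mask = NULL) {
  if (!"analysable" %in% names(table) || anyNA(table$analysable))
    abort("tile table lacks a populated `analysable` flag")
  keep <- table$analysable
  if (!is.null(annotation_mask)) {
    assert_mask(annotation_mask, "annotation_mask")
    cx <- floor(table$x0 + table$tile_size / 2)
    cy <- floor(table$y0 + table$tile_size / 2)
    inside <- annotation_mask[cbind(cy + 1, cx + 1)]
    keep <- keep & inside
  }
  sum(keep)
}

#' Slide-level QC report
#'
#' Bundles the three QC quantities for one slide: dominant colour (RGB and
#' CIELAB), bone area and analysable tile count.
#'
#' @param image 8-bit RGB array.
#' @param tissue_mask,bone_mask Logical matrices.
#' @param tile_table `tile_table` with the analysability flag.
#' @param mpp Microns per pixel.
#' @param id Slide identifier.
#' @return One-row tibble: `id`, `r`, `g`, `b`, `L`, `a_star`, `b_star`,
#'   `bone_area_mm2`, `analysable_tiles`.
#' @export
qc_report <- function(image, tissue_mask, bone_mask, tile_table, mpp,
                      id = "slide") {
  dc <- dominant_colour(image, tissue_mask)
  lab <- rgb_to_cielab(dc)
  tibble(id = id, r = dc[["r"]], g = dc[["g"]], b = dc[["b"]],
         L = lab[["L"]], a_star = lab[["a"]], b_star = lab[["b"]],
         bone_area_mm2 = bone_area(bone_mask, mpp),
         analysable_tiles = analysable_tile_count(tile_table))
}

#' Paired cohort comparison of a QC quantity
#'
#' Exact Wilcoxon signed-rank test on per-sample paired values (e.g. bone
#' area on reticulin vs H&E arms of the same samples).
#'
#' @param x,y Paired per-sample values.
#' @return One-row tibble: `mean_x`, `mean_y`, `statistic`, `p_value`.
#' @export
paired_qc_test <- function(x, y) {
  if (length(x) != length(y)) abort("paired vectors must align")
  wt <- wilcox.test(x, y, paired = TRUE, exact = length(x) < 50)
  tibble(mean_x = mean(x), mean_y = mean(y),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}
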