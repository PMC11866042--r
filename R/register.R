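# Affine registration of a stain pair from segmented tissue masks.
#
# The estimator never touches pixel intensities: it aligns the binary
# tissue silhouettes. Initialisation is moment-based (centroid translation,
# principal-axis rotation with its 180-degree ambiguity resolved by overlap,
# isotropic scale from the area ratio), followed by Nelder-Mead refinement
# of (rotation, log-scale, translation) maximising mask intersection-over-
# union in the destination frame.

mask_moments <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) abort("mask is empty")
  h <- nrow(mask)
  x <- (idx - 1) %/% h
  y <- (idx - 1) %% h
  cx <- mean(x); cy <- mean(y)
  sxx <- mean((x - cx)^2); syy <- mean((y - cy)^2); sxy <- mean((x - cx) * (y - cy))
  theta <- 0.5 * atan2(2 * sxy, sxx - syy)
  list(cx = cx, cy = cy, area = length(idx), theta = theta)
}

mask_iou <- function(warped, dst) {
  inter <- sum(warped & dst)
  uni <- sum(warped | dst)
  if (uni == 0) 0 else inter / uni
}

# IoU of src warped through the similarity defined by (theta, log s, tx, ty)
# about the source centroid onto the destination centroid.
overlap_objective <- function(par, src, dst, msrc, mdst) {
  t <- similarity_about(par, msrc, mdst)
  w <- warp_matrix(src * 1, t, dim(dst), interp = "nearest") > 0.5
  mask_iou(w, dst)
}

similarity_about <- function(par, msrc, mdst) {
  th <- par[1]; s <- exp(par[2])
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) * s
  csrc <- c(msrc$cx, msrc$cy)
  cdst <- c(mdst$cx + par[3], mdst$cy + par[4])
  affine_transform(cbind(rot, cdst - rot %*% csrc))
}

#' Estimate the affine transform aligning two tissue masks
#'
#' @param mask_src Source-frame (reticulin) tissue mask, logical matrix.
#' @param mask_dst Destination-frame (H&E) tissue mask.
#' @param refine Run Nelder-Mead IoU refinement after the moment
#'   initialisation (default TRUE).
#' @param iou_floor Final IoU below this flags the registration as failed
#'   (attribute `failed`; default floor 0.5).
#' @param refine_px Masks larger than this on their longest side are
#'   subsampled for the refinement objective only (moments and the final
#'   IoU stay full-resolution); keeps refinement fast on slide-sized
#'   masks without affecting sub-pixel accuracy of the initialisation.
#' @return An `affine_transform` mapping source to destination pixel
#'   coordinates, with attributes `iou` (final mask IoU) and `failed`.
#' @export
estimate_affine <- function(mask_src, mask_dst, refine = TRUE, iou_floor = 0.5,
                            refine_px = 384L) {
  assert_mask(mask_src, "mask_src"); assert_mask(mask_dst, "mask_dst")
  msrc <- mask_moments(mask_src)
  mdst <- mask_moments(mask_dst)
  s0 <- 0.5 * log(mdst$area / msrc$area)
  dth <- mdst$theta - msrc$theta
  f <- max(1L, ceiling(max(dim(mask_src), dim(mask_dst)) / refine_px))
  src_ds <- mask_src[seq(1, nrow(mask_src), by = f),
                     seq(1, ncol(mask_src), by = f)]
  dst_ds <- mask_dst[seq(1, nrow(mask_dst), by = f),
                     seq(1, ncol(mask_dst), by = f)]
  msrc_ds <- mask_moments(src_ds); mdst_ds <- mask_moments(dst_ds)
  # Principal axis is defined modulo pi, and boundary clipping can bias it:
  # scan a small rotation grid around both orientations on the coarse masks.
  grid <- (c(outer(c(dth, dth + pi), seq(-6, 6, by = 2) * pi / 180, "+")))
  grid <- atan2(sin(grid), cos(grid))
  best <- NULL
  for (th in grid) {
    iou <- overlap_objective(c(th, s0, 0, 0), src_ds, dst_ds, msrc_ds, mdst_ds)
    if (is.null(best) || iou > best$iou) best <- list(th = th, iou = iou)
  }
  par <- c(best$th, s0, 0, 0)
  iou <- overlap_objective(par, mask_src, mask_dst, msrc, mdst)
  if (refine) {
    if (f > 1L) {
      opt <- optim(c(par[1:2], par[3:4] / f),
                   function(p) -overlap_objective(p, src_ds, dst_ds, msrc_ds, mdst_ds),
                   method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-6,
                                  parscale = c(0.02, 0.02, 2, 2)))
      cand_par <- c(opt$par[1:2], opt$par[3:4] * f)
    } else {
      opt <- optim(par, function(p) -overlap_objective(p, mask_src, mask_dst, msrc, mdst),
                   method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-6,
                                  parscale = c(0.02, 0.02, 2, 2)))
      cand_par <- opt$par
    }
    cand_iou <- overlap_objective(cand_par, mask_src, mask_dst, msrc, mdst)
    if (cand_iou >= iou) { par <- cand_par; iou <- cand_iou }
  }
  t <- similarity_about(par, msrc, mdst)
  attr(t, "iou") <- iou
  attr(t, "failed") <- iou < iou_floor
  t
}

#' Pair source-grid tiles with destination tiles through a transform
#'
#' Each source tile centre is mapped through `t`; the destination tile of
#' the same pixel size is centred on the mapped centre (rounded to integer
#' pixels). Pairs whose destination footprint leaves the canvas are
#' dropped. Destination pixels are taken as-is (no resampling), preserving
#' native texture for training.
#'
#' @param src_table `tile_table` on the source image grid.
#' @param t `affine_transform` mapping source to destination coordinates.
#' @param dst_image Destination RGB array (bounds and, if `extract`,
#'   pixels).
#' @param src_image Optional source RGB array; when given together with
#'   `extract = TRUE`, both tile images are attached as list columns.
#' @param extract Attach tile pixel arrays (default FALSE: coordinates
#'   only).
#' @return A tibble with the source tile columns plus `dst_x0`, `dst_y0`
#'   (and list columns `src_tile`, `dst_tile` when extracted). The `label`
#'   column, if present, is carried through.
#' @export
pair_tiles <- function(src_table, t, dst_image, src_image = NULL,
                       extract = FALSE) {
  stopifnot(inherits(t, "affine_transform"))
  assert_image(dst_image, "dst_image")
  h <- dim(dst_image)[1]; w <- dim(dst_image)[2]
  ts <- src_table$tile_size
  centres <- tibble(x = src_table$x0 + ts / 2, y = src_table$y0 + ts / 2)
  mapped <- map_coords(t, centres)
  out <- src_table |>
    mutate(dst_x0 = as.integer(round(mapped$x - ts / 2)),
           dst_y0 = as.integer(round(mapped$y - ts / 2))) |>
    filter(.data$dst_x0 >= 0, .data$dst_y0 >= 0,
           .data$dst_x0 + .data$tile_size <= w,
           .data$dst_y0 + .data$tile_size <= h)
  if (nrow(out) == 0)
    abort("all mapped tiles fall outside the destination canvas")
  if (extract) {
    out$dst_tile <- purrr::pmap(list(out$dst_x0, out$dst_y0, out$tile_size),
                                function(x0, y0, t) crop_tile(dst_image, x0, y0, t))
    if (!is.null(src_image))
      out$src_tile <- purrr::pmap(list(out$x0, out$y0, out$tile_size),
                                  function(x0, y0, t) crop_tile(src_image, x0, y0, t))
  }
  as_tibble(out)
}
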