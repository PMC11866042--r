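# Synthetic paired-stain phantom slides.
#
# Every downstream stage (masking, registration, tiling, ranking model, QC,
# subsampling) is exercised against these phantoms, whose latent fibrosis
# severity, tissue compartments, stain-pair misalignment and stain drift are
# all known exactly. The rendering is deliberately schematic: curvilinear
# dark strokes stand in for reticulin fibres, eosinophilic streaks for their
# H&E correlate, white ellipses for fat vacuoles and pale rimmed blobs for
# bone trabeculae. Nothing claims histological realism; the point is a
# learnable texture signal tied to a known latent field.

# Rendering palette (8-bit RGB). Background is scanner white.
.phantom_colours <- list(
  background = c(245, 245, 245),
  he_tissue  = c(210, 165, 195),
  he_stroke  = c(150, 60, 110),
  he_bone    = c(232, 205, 212),
  he_rim     = c(195, 155, 170),
  ret_tissue = c(212, 205, 192),
  ret_stroke = c(45, 38, 32),
  ret_bone   = c(226, 216, 200),
  ret_rim    = c(180, 170, 150),
  fat        = c(251, 251, 251)
)

#' Specify a synthetic paired-stain phantom
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param mpp Microns per pixel (> 0). The default canvas of 2048 px at
#'   0.22 mpp makes a 512-px tile span about 113 um.
#' @param fibrosis_field Latent severity field description: either
#'   `list(type = "constant", value = v)` with `v` in \[0, 1\], or
#'   `list(type = "random", mean =, amplitude =, correlation_length_px =)`
#'   for a smoothed Gaussian random field (clamped to \[0, 1\]).
#' @param n_bone_blobs Number of bone trabecula blobs (>= 0).
#' @param fat_fraction Target fat area as a fraction of tissue area, in
#'   \[0, 1).
#' @param misalignment `list(rotation_deg =, translation_px = c(tx, ty),
#'   scale =)`: the true affine mapping the reticulin frame to the H&E
#'   frame (rotation/scale about the canvas centre, then translation).
#' @param stain_drift_sd Standard deviation of the global per-channel
#'   additive colour shift applied to each rendering. A single number is
#'   used for both stains; a named vector `c(reticulin =, he =)` sets them
#'   separately.
#' @param bone_loss_fraction Fraction of bone area eroded in the
#'   pseudo-reticulin rendering, in \[0, 1\].
#' @param stroke_density Expected fibre-stroke seeds per pixel of stroma at
#'   severity 1; controls texture density.
#' @param tissue_radii Semi-axes of the tissue ellipse as fractions of the
#'   canvas width and height. The default nearly fills the canvas; smaller
#'   values leave margin for large misalignments.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec (seed included).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width_px = 2048, height_px = 2048, mpp = 0.22,
                         fibrosis_field = list(type = "random", mean = 0.5,
                                               amplitude = 0.3,
                                               correlation_length_px = width_px / 4),
                         n_bone_blobs = 3, fat_fraction = 0.1,
                         misalignment = list(rotation_deg = 0,
                                             translation_px = c(0, 0),
                                             scale = 1),
                         stain_drift_sd = 0, bone_loss_fraction = 0,
                         stroke_density = 0.01, tissue_radii = c(0.44, 0.35),
                         seed = 1L) {
  if (width_px < 32 || height_px < 32)
    abort("phantom canvas must be at least 32 x 32 px")
  if (mpp <= 0) abort("`mpp` must be > 0")
  if (!is.list(fibrosis_field) || is.null(fibrosis_field$type))
    abort("`fibrosis_field` must be a list with a `type` field")
  if (fibrosis_field$type == "constant" &&
      (fibrosis_field$value < 0 || fibrosis_field$value > 1))
    abort("constant fibrosis value must lie in [0, 1]")
  if (n_bone_blobs < 0) abort("`n_bone_blobs` must be >= 0")
  if (fat_fraction < 0 || fat_fraction >= 1)
    abort("`fat_fraction` must lie in [0, 1)")
  if (bone_loss_fraction < 0 || bone_loss_fraction > 1)
    abort("`bone_loss_fraction` must lie in [0, 1]")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), mpp = mpp,
                 fibrosis_field = fibrosis_field,
                 n_bone_blobs = as.integer(n_bone_blobs),
                 fat_fraction = fat_fraction, misalignment = misalignment,
                 stain_drift_sd = stain_drift_sd,
                 bone_loss_fraction = bone_loss_fraction,
                 stroke_density = stroke_density,
                 tissue_radii = tissue_radii,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Elliptical blob mask with a low-frequency wobbled boundary.
blob_mask <- function(h, w, cx, cy, rx, ry, wobble = 0, theta0 = 0) {
  m <- matrix(FALSE, h, w)
  m[blob_indices(h, w, cx, cy, rx, ry, wobble, theta0)] <- TRUE
  m
}

# Linear indices of the same blob, computed only over its bounding box.
blob_indices <- function(h, w, cx, cy, rx, ry, wobble = 0, theta0 = 0) {
  rmax <- max(rx, ry) * (1 + wobble)
  x0 <- max(0, floor(cx - rmax)); x1 <- min(w - 1, ceiling(cx + rmax))
  y0 <- max(0, floor(cy - rmax)); y1 <- min(h - 1, ceiling(cy + rmax))
  if (x1 < x0 || y1 < y0) return(integer(0))
  bx <- rep(x0:x1, each = y1 - y0 + 1); by <- rep(y0:y1, times = x1 - x0 + 1)
  dx <- (bx - cx) / rx; dy <- (by - cy) / ry
  r2 <- dx * dx + dy * dy
  if (wobble > 0) {
    ang <- atan2(dy, dx)
    r2 <- r2 / (1 + wobble * sin(3 * ang + theta0))^2
  }
  inside <- r2 <= 1
  (by[inside] + 1) + bx[inside] * h
}

# Smoothed latent field in [0,1] via bilinear upsampling of coarse noise.
latent_field <- function(ff, h, w) {
  if (ff$type == "constant") return(matrix(ff$value, h, w))
  if (ff$type != "random") abort("unknown fibrosis_field type")
  cl <- max(8, ff$correlation_length_px %||% (w / 4))
  ch <- max(2L, ceiling(h / cl) + 1L); cw <- max(2L, ceiling(w / cl) + 1L)
  coarse <- matrix(rnorm(ch * cw), ch, cw)
  f <- upsample_bilinear(coarse, h, w)
  f <- (ff$mean %||% 0.5) + (ff$amplitude %||% 0.3) * f
  clamp(f, 0, 1)
}

# One curvilinear fibre stroke: a random walk of `steps` unit-ish segments
# starting at (x0, y0); returns 0-based pixel coords (2 px wide).
stroke_pixels <- function(x0, y0, steps, step_len = 1.4, turn_sd = 0.35) {
  th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(steps - 1, 0, turn_sd)))
  xs <- x0 + cumsum(step_len * cos(th))
  ys <- y0 + cumsum(step_len * sin(th))
  px <- round(c(xs, xs + 1)); py <- round(c(ys, ys))
  cbind(px, py)
}

#' Generate a synthetic paired-stain phantom
#'
#' Renders an H&E-like and a reticulin-like image of the same virtual
#' tissue section. Both carry fibre texture whose local density is a
#' monotone function of the shared latent fibrosis field; the reticulin
#' rendering lives in its own frame related to the H&E frame by exactly
#' `true_affine`, loses `bone_loss_fraction` of its bone area (eroded from
#' each trabecula's rim inward), and each rendering receives an independent
#' global per-channel colour shift drawn with `stain_drift_sd`.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_pair` list: `he_image`, `reticulin_image` (8-bit RGB
#'   arrays), `fibrosis_field` (\[0, 1\] matrix, H&E frame), `tissue_mask`,
#'   `bone_mask`, `fat_mask` (logical, H&E frame), `reticulin_tissue_mask`,
#'   `reticulin_bone_mask` (logical, reticulin frame), `true_affine`
#'   (reticulin frame -> H&E frame), `stain_shift` (per-stain drift
#'   actually applied), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  h <- spec$height_px; w <- spec$width_px
  cols <- .phantom_colours

  # Tissue: anisotropic wobbled ellipse. Anisotropy keeps the principal
  # axis of the mask well defined, which mask-based registration relies on.
  tr <- spec$tissue_radii %||% c(0.44, 0.35)
  tissue <- blob_mask(h, w, cx = (w - 1) / 2, cy = (h - 1) / 2,
                      rx = tr[1] * w, ry = tr[2] * h,
                      wobble = 0.05, theta0 = runif(1, 0, 2 * pi))

  field <- latent_field(spec$fibrosis_field, h, w)

  # Bone trabeculae: rimmed pale blobs, kept inside the tissue.
  bone <- matrix(FALSE, h, w)
  bone_blobs <- list()
  if (spec$n_bone_blobs > 0) {
    for (b in seq_len(spec$n_bone_blobs)) {
      r <- runif(1, 0.05, 0.09) * min(h, w)
      cx <- runif(1, 0.25 * w, 0.75 * w); cy <- runif(1, 0.25 * h, 0.75 * h)
      bm <- blob_mask(h, w, cx, cy, r * runif(1, 0.8, 1.3), r,
                      wobble = 0.12, theta0 = runif(1, 0, 2 * pi)) & tissue
      bone_blobs[[b]] <- list(mask = bm, cx = cx, cy = cy)
      bone <- bone | bm
    }
  }

  # Fat vacuoles: white ellipses in stroma, disjoint from bone.
  fat <- matrix(FALSE, h, w)
  tissue_area <- sum(tissue)
  target_fat <- spec$fat_fraction * tissue_area
  fat_area <- 0L
  tries <- 0L
  while (fat_area < target_fat && tries < 1000L) {
    tries <- tries + 1L
    r <- runif(1, 0.015, 0.035) * min(h, w)
    cx <- runif(1, 0, w - 1); cy <- runif(1, 0, h - 1)
    if (!tissue[round(cy) + 1, round(cx) + 1]) next
    idx <- blob_indices(h, w, cx, cy, r * runif(1, 0.8, 1.2), r)
    idx <- idx[tissue[idx]]
    if (any(bone[idx])) next
    fat[idx] <- TRUE
    fat_area <- sum(fat)
  }

  stroma <- tissue & !bone & !fat

  # Base renderings in the shared (H&E) frame.
  base_img <- function(tissue_col, bone_col, rim_col) {
    img <- array(0, c(h, w, 3))
    for (c in 1:3) {
      ch <- matrix(cols$background[c], h, w)
      ch[tissue] <- tissue_col[c]
      ch[fat] <- cols$fat[c]
      ch[bone] <- bone_col[c]
      img[, , c] <- ch
    }
    img
  }
  he <- base_img(cols$he_tissue, cols$he_bone, cols$he_rim)
  ret <- base_img(cols$ret_tissue, cols$ret_bone, cols$ret_rim)

  # Bone rims: boundary band of each blob.
  if (any(bone)) {
    eroded <- ebi_erode(bone, 5L)
    rim <- bone & !eroded
    rim_idx <- which(rim)
    for (c in 1:3) {
      he[, , c][rim_idx] <- cols$he_rim[c]
      ret[, , c][rim_idx] <- cols$ret_rim[c]
    }
  }

  # Fibre strokes. Candidate seeds are drawn once and accepted with
  # probability equal to the local latent severity, so for the same seed a
  # higher severity accepts a superset of candidates (monotone rendering).
  stroma_idx <- which(stroma)
  if (length(stroma_idx) > 0 && spec$stroke_density > 0) {
    n_cand <- max(1L, round(spec$stroke_density * length(stroma_idx)))
    cand <- sample(stroma_idx, n_cand, replace = TRUE)
    u <- runif(n_cand)
    cy0 <- (cand - 1) %% h; cx0 <- (cand - 1) %/% h
    steps <- sample(15:35, n_cand, replace = TRUE)
    stroke_idx <- vector("list", n_cand)
    for (i in seq_len(n_cand)) {
      px <- stroke_pixels(cx0[i], cy0[i], steps[i])
      if (u[i] >= field[cand[i]]) next  # after RNG use: keeps streams aligned
      keep <- px[, 1] >= 0 & px[, 1] < w & px[, 2] >= 0 & px[, 2] < h
      px <- px[keep, , drop = FALSE]
      idx <- px[, 2] + 1 + px[, 1] * h
      stroke_idx[[i]] <- idx[stroma[idx]]
    }
    idx <- unique(unlist(stroke_idx))
    if (length(idx) > 0) {
      n <- h * w
      for (c in 1:3) {
        he[idx + (c - 1) * n] <- cols$he_stroke[c]
        ret[idx + (c - 1) * n] <- cols$ret_stroke[c]
      }
    }
  }

  # Bone loss in the pseudo-reticulin rendering: per blob, keep the
  # (1 - f) fraction of pixels nearest the blob centroid (rim erodes first).
  ret_bone_aligned <- bone
  f_loss <- spec$bone_loss_fraction
  if (f_loss > 0 && any(bone)) {
    for (bl in bone_blobs) {
      idx <- which(bl$mask)
      if (length(idx) == 0) next
      py <- (idx - 1) %% h; px <- (idx - 1) %/% h
      d <- (px - bl$cx)^2 + (py - bl$cy)^2
      n_keep <- round((1 - f_loss) * length(idx))
      drop_idx <- idx[order(d, idx)][-seq_len(n_keep)]
      if (n_keep == 0) drop_idx <- idx
      ret_bone_aligned[drop_idx] <- FALSE
      for (c in 1:3) ret[, , c][drop_idx] <- cols$ret_tissue[c]
    }
  }

  # True misalignment: reticulin frame -> H&E frame.
  mis <- spec$misalignment
  true_affine <- affine_from_params(
    rotation_deg = mis$rotation_deg %||% 0,
    translation = mis$translation_px %||% c(0, 0),
    scale = mis$scale %||% 1,
    centre = c((w - 1) / 2, (h - 1) / 2))

  # Render the reticulin frame: ret_frame[p] = ret_aligned[true_affine(p)].
  ret_frame <- warp_image(ret, affine_invert(true_affine), c(h, w),
                          interp = "bilinear", fill = cols$background[1])
  ret_tissue_frame <- warp_matrix(tissue * 1, affine_invert(true_affine),
                                  c(h, w), interp = "nearest") > 0.5
  ret_bone_frame <- warp_matrix(ret_bone_aligned * 1, affine_invert(true_affine),
                                c(h, w), interp = "nearest") > 0.5
  if (!any(ret_tissue_frame))
    abort("misalignment maps all tissue off-canvas; reduce translation/scale")

  # Global per-slide stain drift, one additive shift per channel per stain.
  sd_vec <- spec$stain_drift_sd
  sd_ret <- if (length(sd_vec) > 1) sd_vec[["reticulin"]] else sd_vec
  sd_he <- if (length(sd_vec) > 1) sd_vec[["he"]] else sd_vec
  shift_he <- if (sd_he > 0) rnorm(3, 0, sd_he) else c(0, 0, 0)
  shift_ret <- if (sd_ret > 0) rnorm(3, 0, sd_ret) else c(0, 0, 0)
  for (c in 1:3) {
    he[, , c] <- he[, , c] + shift_he[c]
    ret_frame[, , c] <- ret_frame[, , c] + shift_ret[c]
  }

  structure(list(he_image = as_uint8(he),
                 reticulin_image = as_uint8(ret_frame),
                 fibrosis_field = field,
                 tissue_mask = tissue, bone_mask = bone, fat_mask = fat,
                 reticulin_tissue_mask = ret_tissue_frame,
                 reticulin_bone_mask = ret_bone_frame,
                 true_affine = true_affine,
                 stain_shift = list(he = shift_he, reticulin = shift_ret),
                 spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<phantom_pair> %d x %d px @ %.3g mpp; tissue %.0f%%, bone %.1f%%, fat %.1f%%\n",
              s$width_px, s$height_px, s$mpp,
              100 * mean(x$tissue_mask), 100 * mean(x$bone_mask),
              100 * mean(x$fat_mask)))
  invisible(x)
}

#' Ground-truth per-tile fibrosis labels from a phantom
#'
#' The label of each tile is the mean of the phantom's latent fibrosis
#' field over the tile footprint, in \[0, 1\]. On phantoms this plays the
#' role of the teacher model that scores tiles in the paired-stain
#' training procedure.
#'
#' @param pair A `phantom_pair`.
#' @param tile_table A tile table from [extract_tiles()] (columns `index`,
#'   `x0`, `y0`, `tile_size`).
#' @return The tile table with a `label` column appended.
#' @export
ground_truth_tile_labels <- function(pair, tile_table) {
  stopifnot(inherits(pair, "phantom_pair"))
  f <- pair$fibrosis_field
  h <- nrow(f); w <- ncol(f)
  labels <- purrr::pmap_dbl(
    list(tile_table$index, tile_table$x0, tile_table$y0, tile_table$tile_size),
    function(index, x0, y0, t) {
      if (x0 < 0 || y0 < 0 || x0 + t > w || y0 + t > h)
        abort(sprintf("tile %s lies outside the raster", index))
      tile_sum(f, x0, y0, t) / (t * t)
    })
  dplyr::mutate(tile_table, label = labels)
}

#' Write a phantom pair to disk
#'
#' Images and masks are written as PNG, the latent field as 32-bit float
#' TIFF, and the true affine plus spec as a JSON sidecar.
#'
#' @param pair A `phantom_pair`.
#' @param dir Output directory (created if needed).
#' @param id Sample identifier used as the filename stem.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_phantom <- function(pair, dir, id = "phantom") {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(dir, paste0(id, "_", suffix))
  paths <- list(he = p("he.png"), reticulin = p("reticulin.png"),
                tissue_mask = p("tissue_mask.png"),
                bone_mask = p("bone_mask.png"), fat_mask = p("fat_mask.png"),
                ret_tissue_mask = p("ret_tissue_mask.png"),
                ret_bone_mask = p("ret_bone_mask.png"),
                field = p("field.tif"), sidecar = p("sidecar.json"))
  write_image_png(pair$he_image, paths$he)
  write_image_png(pair$reticulin_image, paths$reticulin)
  write_mask_png(pair$tissue_mask, paths$tissue_mask)
  write_mask_png(pair$bone_mask, paths$bone_mask)
  write_mask_png(pair$fat_mask, paths$fat_mask)
  write_mask_png(pair$reticulin_tissue_mask, paths$ret_tissue_mask)
  write_mask_png(pair$reticulin_bone_mask, paths$ret_bone_mask)
  tiff::writeTIFF(pair$fibrosis_field, paths$field, bits.per.sample = 32)
  side <- list(true_affine = pair$true_affine$matrix,
               spec = unclass(pair$spec))
  jsonlite::write_json(side, paths$sidecar, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(paths)
}
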