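# Tissue masking, fixed-grid tile extraction and the analysability filter.
#
# Tiles are 512 x 512 px by default, which at 0.22 microns per pixel spans
# about 113 um of tissue — the working scale for marrow fibrosis texture.
# The analysability rule keeps intertrabecular tiles only: fat below 50%
# and bone below 1% of the tile area, both strict.

#' Segment tissue from background by thresholding
#'
#' Classical luminance/saturation thresholding: a pixel is foreground when
#' it is either darker than near-white background or visibly coloured.
#' The raw mask is cleaned by morphological closing, hole filling (fat
#' vacuoles inside tissue count as tissue) and small-object removal.
#'
#' @param image 8-bit RGB array.
#' @param luminance_max Foreground luminance threshold (Rec. 601 luma).
#' @param saturation_min Foreground chroma threshold (max - min channel).
#' @param close_size Structuring-element diameter for closing, px.
#' @param min_object_px Connected components smaller than this are dropped.
#' @return Logical matrix the size of the image.
#' @export
compute_tissue_mask <- function(image, luminance_max = 235,
                                saturation_min = 20, close_size = 7L,
                                min_object_px = 256L) {
  assert_image(image)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  luma <- 0.299 * r + 0.587 * g + 0.114 * b
  sat <- pmax(r, g, b) - pmin(r, g, b)
  fg <- luma < luminance_max | sat > saturation_min
  if (!any(fg)) return(fg)
  fg <- ebi_close(fg, close_size)
  fg <- EBImage::fillHull(fg * 1) > 0.5
  lab <- EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object_px)
  matrix(lab %in% keep, nrow = nrow(fg), ncol = ncol(fg))
}

#' Extract a fixed grid of tissue tiles
#'
#' Lays a non-overlapping tile grid anchored at the image origin (partial
#' edge tiles are discarded) and keeps tiles whose tissue fraction reaches
#' `min_tissue_fraction`. Fractions are exact pixel counts over each
#' half-open tile footprint.
#'
#' @param image 8-bit RGB array (used for bounds; may be NULL if
#'   `tissue_mask` is given).
#' @param tissue_mask Logical matrix; computed with [compute_tissue_mask()]
#'   when missing.
#' @param tile_size Tile side in pixels (default 512).
#' @param min_tissue_fraction Minimum tissue fraction for a tile to be kept
#'   (default 0.5).
#' @param fat_mask,bone_mask Optional logical matrices; when supplied the
#'   per-tile `fat_frac` / `bone_frac` columns are filled and the
#'   `analysable` flag applies the strict fat < 0.50 / bone < 0.01 rule.
#' @return A `tile_table` tibble with columns `index`, `x0`, `y0`,
#'   `tile_size`, `tissue_frac`, `fat_frac`, `bone_frac`, `analysable`.
#' @export
extract_tiles <- function(image = NULL, tissue_mask = NULL, tile_size = 512L,
                          min_tissue_fraction = 0.5,
                          fat_mask = NULL, bone_mask = NULL) {
  if (is.null(tissue_mask)) {
    assert_image(image)
    tissue_mask <- compute_tissue_mask(image)
  }
  assert_mask(tissue_mask, "tissue_mask")
  t <- as.integer(tile_size)
  if (t <= 0) abort("`tile_size` must be positive")
  h <- nrow(tissue_mask); w <- ncol(tissue_mask)
  if (t > h || t > w) abort("`tile_size` exceeds image dimensions")
  x0s <- seq(0L, w - t, by = t)
  y0s <- seq(0L, h - t, by = t)
  grid <- tidyr::expand_grid(y0 = y0s, x0 = x0s)  # row-major, reading order
  tm <- tissue_mask * 1
  fm <- if (!is.null(fat_mask)) fat_mask * 1 else NULL
  bm <- if (!is.null(bone_mask)) bone_mask * 1 else NULL
  area <- t * t
  frac <- function(mat, x0, y0) if (is.null(mat)) NA_real_ else tile_sum(mat, x0, y0, t) / area
  tab <- grid |>
    mutate(tissue_frac = purrr::map2_dbl(.data$x0, .data$y0, ~ tile_sum(tm, .x, .y, t) / area),
           fat_frac = purrr::map2_dbl(.data$x0, .data$y0, ~ frac(fm, .x, .y)),
           bone_frac = purrr::map2_dbl(.data$x0, .data$y0, ~ frac(bm, .x, .y))) |>
    filter(.data$tissue_frac >= min_tissue_fraction) |>
    mutate(index = dplyr::row_number() - 1L, tile_size = t,
           analysable = .data$fat_frac < 0.50 & .data$bone_frac < 0.01) |>
    select("index", "x0", "y0", "tile_size", "tissue_frac", "fat_frac",
           "bone_frac", "analysable")
  new_tile_table(tab, img_dim = c(h, w))
}

new_tile_table <- function(tab, img_dim = NULL) {
  tab <- as_tibble(tab)
  class(tab) <- c("tile_table", class(tab))
  attr(tab, "img_dim") <- img_dim
  tab
}

#' Keep analysable intertrabecular tiles
#'
#' Retains exactly the tiles with `fat_frac < 0.50` and `bone_frac < 0.01`
#' (both strict, so boundary values are excluded). Idempotent.
#'
#' @param table A `tile_table` with populated fat and bone fractions.
#' @return The filtered `tile_table`.
#' @export
filter_analysable <- function(table) {
  if (!all(c("fat_frac", "bone_frac") %in% names(table)))
    abort("tile table lacks `fat_frac`/`bone_frac` columns")
  if (anyNA(table$fat_frac) || anyNA(table$bone_frac))
    abort("fat/bone fractions must be populated before filtering")
  out <- filter(table, .data$fat_frac < 0.50, .data$bone_frac < 0.01)
  new_tile_table(out, img_dim = attr(table, "img_dim"))
}

#' Crop one tile out of an image
#'
#' @param image 8-bit RGB array.
#' @param x0,y0 Top-left pixel, 0-based.
#' @param tile_size Tile side, px.
#' @return The `tile_size` x `tile_size` x 3 sub-array.
#' @export
crop_tile <- function(image, x0, y0, tile_size) {
  assert_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (x0 < 0 || y0 < 0 || x0 + tile_size > w || y0 + tile_size > h)
    abort("tile extends outside the image")
  image[(y0 + 1):(y0 + tile_size), (x0 + 1):(x0 + tile_size), , drop = FALSE]
}

#' Write / read a tile table as CSV
#'
#' @param table A `tile_table`.
#' @param path CSV path.
#' @return `read_tile_table_csv` returns the `tile_table`.
#' @export
write_tile_table_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_table_csv
#' @export
read_tile_table_csv <- function(path) {
  new_tile_table(read.csv(path))
}
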