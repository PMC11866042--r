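# CIF maps: per-tile continuous fibrosis scores on a slide grid, their
# slide-level aggregate, comparison metrics and false-colour rendering.

new_cif_map <- function(tab) {
  tab <- as_tibble(tab)
  if (!"cif" %in% names(tab)) abort("a cif_map needs a `cif` column")
  if (any(tab$cif < 0 | tab$cif > 1)) abort("CIF scores must lie in [0, 1]")
  class(tab) <- c("cif_map", setdiff(class(tab), "cif_map"))
  tab
}

#' Construct a CIF map from per-tile scores
#'
#' @param index Tile indices.
#' @param x0,y0 Tile top-left pixel coordinates (0-based).
#' @param cif Scores in \[0, 1\].
#' @param tile_size Tile side, px.
#' @return A `cif_map` tibble.
#' @export
cif_map <- function(index, x0, y0, cif, tile_size = 512L) {
  new_cif_map(tibble(index = index, x0 = x0, y0 = y0,
                     tile_size = tile_size, cif = cif))
}

#' Slide-level aggregate CIF
#'
#' The sample score is the arithmetic mean of the per-tile CIF scores.
#'
#' @param map A `cif_map`.
#' @return A single number in \[0, 1\].
#' @export
cif_aggregate <- function(map) mean(map$cif)

#' Write / read a CIF map as CSV
#'
#' @param map A `cif_map`.
#' @param path CSV path.
#' @return `read_cif_map_csv` returns the `cif_map`.
#' @export
write_cif_map_csv <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cif_map_csv
#' @export
read_cif_map_csv <- function(path) new_cif_map(read.csv(path))

#' Pairwise prediction accuracy of a score vector against labels
#'
#' The fraction of ordered label pairs separated by at least `delta` whose
#' predicted scores are concordantly ordered (strictly; predicted ties
#' count as discordant). This is the natural accuracy for a model trained
#' with ordinal supervision.
#'
#' @param pred Predicted scores.
#' @param truth Reference labels on the same tiles.
#' @param delta Minimum label gap defining a qualifying pair (default 0.1).
#' @return Fraction in \[0, 1\].
#' @export
pairwise_prediction_accuracy <- function(pred, truth, delta = 0.1) {
  if (length(pred) != length(truth)) abort("`pred` and `truth` must align")
  d <- outer(truth, truth, "-")
  qual <- d >= delta
  if (!any(qual)) abort("no label pair is separated by >= delta")
  conc <- outer(pred, pred, ">")
  sum(conc & qual) / sum(qual)
}

#' Mean absolute CIF difference between two maps
#'
#' @param map_a,map_b `cif_map`s sharing tile indices.
#' @return One-row tibble: `mean_abs_diff`, `sd_abs_diff`, `n_tiles`.
#' @export
mean_cif_difference <- function(map_a, map_b) {
  j <- inner_join(as_tibble(map_a)[, c("index", "cif")],
                  as_tibble(map_b)[, c("index", "cif")],
                  by = "index", suffix = c("_a", "_b"))
  if (nrow(j) == 0) abort("the two maps share no tile indices")
  d <- abs(j$cif_a - j$cif_b)
  tibble(mean_abs_diff = mean(d),
         sd_abs_diff = if (nrow(j) > 1) sd(d) else 0,
         n_tiles = nrow(j))
}

#' Render a CIF map as a false-colour overlay
#'
#' Each scored tile is painted with the colour of its CIF value under a
#' fixed viridis colormap over \[0, 1\]; regions without a scored tile
#' (background, non-analysable tissue) are left as the underlying image.
#'
#' @param map A `cif_map` with tile geometry.
#' @param image RGB array the map was computed on.
#' @param alpha Overlay opacity in \[0, 1\] (1 = solid tile colours).
#' @param palette Colour vector indexed by CIF (default 256-step viridis).
#' @return RGB array with the overlay applied.
#' @export
render_heatmap <- function(map, image, alpha = 1,
                           palette = hcl.colors(256, "viridis")) {
  assert_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (any(map$x0 < 0 | map$y0 < 0 | map$x0 + map$tile_size > w |
          map$y0 + map$tile_size > h))
    abort("map geometry does not fit the image")
  cols_rgb <- col2rgb(palette)
  out <- image * 1
  for (i in seq_len(nrow(map))) {
    t <- map$tile_size[i]
    ci <- clamp(floor(map$cif[i] * length(palette)) + 1, 1, length(palette))
    rows <- (map$y0[i] + 1):(map$y0[i] + t)
    cols_ <- (map$x0[i] + 1):(map$x0[i] + t)
    for (c in 1:3)
      out[rows, cols_, c] <- (1 - alpha) * out[rows, cols_, c] + alpha * cols_rgb[c, ci]
  }
  as_uint8(out)
}

#' Plot a CIF map as a ggplot heatmap
#'
#' @param object A `cif_map`.
#' @param ... Unused.
#' @return A ggplot object (tile grid coloured by CIF, viridis scale over
#'   \[0, 1\], y axis flipped to image orientation).
#' @exportS3Method ggplot2::autoplot
autoplot.cif_map <- function(object, ...) {
  t <- object$tile_size %||% 1
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$x0 + .data$tile_size / 2,
    y = .data$y0 + .data$tile_size / 2, fill = .data$cif)) +
    ggplot2::geom_tile(width = t, height = t) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "CIF") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
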