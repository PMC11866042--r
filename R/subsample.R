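# Fibrosis heterogeneity and biopsy adequacy by spatial subsampling.
#
# A trephine core samples a limited region of the marrow; how far a small
# biopsy's CIF can stray from the whole-sample score bounds the adequacy
# of a given specimen size. The analysis draws contiguous subsamples of
# the analysable area at fixed area fractions (default 2/15 ... 10/15),
# records each subsample's mean CIF against the whole-sample CIF, and
# labels a sample heterogeneous when any smallest-fraction subsample
# deviates by more than 0.1 (strict) from the whole-sample score.

#' Draw one spatial subsample of a CIF map
#'
#' A centre tile is chosen uniformly among the map's tiles, and the region
#' grows by repeatedly adding the tile nearest the centre (Euclidean
#' distance between tile centres, ties broken by tile index) until
#' `round(fraction * N)` tiles are included. Contiguity across mask gaps
#' is not enforced: area ratio is measured in tile counts, the support of
#' the CIF map.
#'
#' @param map A `cif_map` with tile geometry.
#' @param fraction Target area fraction in (0, 1\].
#' @param seed Optional seed for the centre draw.
#' @param centre Optional 1-based row index of the centre tile (overrides
#'   the random draw; used by the exhaustive tests).
#' @return The subset of `map` rows forming the subsample, with attribute
#'   `centre` (the centre row index).
#' @export
draw_subsample <- function(map, fraction, seed = NULL, centre = NULL) {
  n <- nrow(map)
  if (n == 0) abort("CIF map is empty")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1]")
  k <- max(1L, round(fraction * n))
  if (k > n) abort("target tile count exceeds available tiles")
  if (is.null(centre))
    centre <- with_seed(seed, sample.int(n, 1))
  cx <- map$x0 + map$tile_size / 2
  cy <- map$y0 + map$tile_size / 2
  d <- (cx - cx[centre])^2 + (cy - cy[centre])^2
  pick <- order(d, map$index)[seq_len(k)]
  out <- map[pick, ]
  attr(out, "centre") <- centre
  out
}

#' Subsampling deviation curves for one slide
#'
#' For each fraction, draws `draws` independent subsamples and records the
#' subsample mean CIF and its absolute deviation from the whole-sample
#' CIF.
#'
#' @param map A `cif_map`.
#' @param fractions Area fractions (default `c(2, 4, 6, 8, 10) / 15`).
#' @param draws Subsamples per fraction (default 20).
#' @param seed RNG seed; the whole curve is reproducible given it.
#' @return A `subsample_result` tibble with columns `fraction`, `draw`,
#'   `centre`, `subsample_cif`, `deviation`; attributes `whole_cif`,
#'   `fractions`, `draws`, `seed`.
#' @export
deviation_curve <- function(map, fractions = c(2, 4, 6, 8, 10) / 15,
                            draws = 20L, seed = 1L) {
  if (draws < 1) abort("`draws` must be >= 1")
  whole <- cif_aggregate(map)
  rows <- with_seed(seed, {
    purrr::map(fractions, function(f) {
      purrr::map(seq_len(draws), function(d) {
        sub <- draw_subsample(map, f)
        tibble(fraction = f, draw = d, centre = attr(sub, "centre"),
               subsample_cif = mean(sub$cif),
               deviation = abs(mean(sub$cif) - whole))
      }) |> bind_rows()
    }) |> bind_rows()
  })
  structure(rows, whole_cif = whole, fractions = fractions, draws = draws,
            seed = seed, class = c("subsample_result", class(rows)))
}

#' Maximum deviation per fraction
#'
#' @param result A `subsample_result`.
#' @return Tibble `fraction`, `max_deviation`.
#' @export
max_deviation_by_fraction <- function(result) {
  result |> group_by(.data$fraction) |>
    summarise(max_deviation = max(.data$deviation), .groups = "drop") |>
    arrange(.data$fraction)
}

#' Classify a sample as heterogeneous or homogeneous for fibrosis
#'
#' Heterogeneous iff any subsample at the smallest fraction deviates by
#' strictly more than `threshold` from the whole-sample CIF; a deviation
#' of exactly the threshold stays homogeneous.
#'
#' @param result A `subsample_result`.
#' @param threshold Deviation threshold (default 0.1).
#' @return `"heterogeneous"` or `"homogeneous"`.
#' @export
classify_heterogeneity <- function(result, threshold = 0.1) {
  fmin <- min(result$fraction)
  dev <- result$deviation[result$fraction == fmin]
  if (length(dev) == 0) abort("no draws at the smallest fraction")
  if (any(dev > threshold)) "heterogeneous" else "homogeneous"
}

#' Cohort summary of subsampling adequacy
#'
#' @param results Named list of `subsample_result`s, one per slide.
#' @param groups Group label per slide (e.g. heterogeneous/homogeneous or
#'   a diagnosis); defaults to one group.
#' @return Tibble `group`, `fraction`, `mean_max_deviation`, `n_slides`,
#'   plus attribute `trend` (per-group Spearman correlation of mean max
#'   deviation with fraction).
#' @export
cohort_adequacy_summary <- function(results, groups = NULL) {
  if (length(results) == 0) abort("empty cohort")
  if (is.null(groups)) groups <- rep("all", length(results))
  if (length(groups) != length(results)) abort("`groups` must align with `results`")
  per_slide <- purrr::imap(results, function(r, i) {
    mutate(max_deviation_by_fraction(r),
           slide = if (is.character(i)) i else as.character(i))
  })
  tab <- bind_rows(purrr::map2(per_slide, groups, ~ mutate(.x, group = .y))) |>
    group_by(.data$group, .data$fraction) |>
    summarise(mean_max_deviation = mean(.data$max_deviation),
              n_slides = n(), .groups = "drop") |>
    arrange(.data$group, .data$fraction)
  trend <- tab |> group_by(.data$group) |>
    summarise(spearman = if (n() > 1 && sd(.data$mean_max_deviation) > 0)
                cor(.data$fraction, .data$mean_max_deviation, method = "spearman")
              else NA_real_, .groups = "drop")
  structure(tab, trend = trend)
}

#' Write a subsample result as JSON
#'
#' @param result A `subsample_result`.
#' @param path JSON path.
#' @param threshold Classification threshold recorded alongside.
#' @return Invisibly, the path.
#' @export
write_subsample_json <- function(result, path, threshold = 0.1) {
  x <- list(whole_cif = attr(result, "whole_cif"),
            fractions = attr(result, "fractions"),
            draws = attr(result, "draws"), seed = attr(result, "seed"),
            threshold = threshold,
            classification = classify_heterogeneity(result, threshold),
            max_deviation = max_deviation_by_fraction(result),
            draws_detail = as.data.frame(result))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Plot subsampling deviation curves
#'
#' @param object A `subsample_result`.
#' @param ... Unused.
#' @return A ggplot: per-draw deviations and the max-deviation curve
#'   against the subsampled area fraction.
#' @exportS3Method ggplot2::autoplot
autoplot.subsample_result <- function(object, ...) {
  mx <- max_deviation_by_fraction(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$fraction, .data$deviation)) +
    ggplot2::geom_jitter(width = 0.008, height = 0, alpha = 0.4) +
    ggplot2::geom_line(data = mx, ggplot2::aes(y = .data$max_deviation),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.1, linetype = 2) +
    ggplot2::labs(x = "subsampled fraction of analysable area",
                  y = "|subsample CIF - whole-sample CIF|") +
    ggplot2::theme_minimal()
}
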