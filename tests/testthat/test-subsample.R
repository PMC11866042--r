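# Spatial subsampling, deviation curves and the heterogeneity call.

grid_map <- function(nx, ny, cif, tile_size = 32L) {
  tab <- grid_tile_table(nx, ny, tile_size)
  cif_map(tab$index, tab$x0, tab$y0, cif, tile_size)
}

half_half_map <- function(n = 8) {
  # left half 0, right half 1
  tab <- grid_tile_table(n, n, 32L)
  cif_map(tab$index, tab$x0, tab$y0, as.numeric(tab$x0 >= n / 2 * 32), 32L)
}

test_that("fraction 1 returns the whole analysable set with zero deviation", {
  m <- grid_map(4, 4, runif(16))
  s <- draw_subsample(m, 1, seed = 5)
  expect_setequal(s$index, m$index)
  r <- deviation_curve(m, fractions = 1, draws = 3, seed = 2)
  expect_true(all(r$deviation == 0))
})

test_that("uniform maps never deviate and classify homogeneous", {
  m <- grid_map(5, 5, rep(0.4, 25))
  r <- deviation_curve(m, draws = 10, seed = 3)
  expect_true(all(r$deviation == 0))
  expect_equal(classify_heterogeneity(r), "homogeneous")
})

test_that("a corner centre grows into its 2 x 2 neighbourhood", {
  m <- grid_map(4, 4, seq(0, 1, length.out = 16))
  s <- draw_subsample(m, 4 / 16, centre = 1)  # top-left tile
  expect_setequal(s$index, c(0L, 1L, 4L, 5L))
})

test_that("draws equal the k-nearest-tile oracle for every centre", {
  set.seed(9)
  tab <- grid_tile_table(9, 7, 32L)[sample(63, 48), ]  # irregular support
  m <- cif_map(tab$index, tab$x0, tab$y0, runif(48), 32L)
  k <- round(0.3 * nrow(m))
  for (centre in seq_len(nrow(m))) {
    s <- draw_subsample(m, 0.3, centre = centre)
    cx <- m$x0 + 16; cy <- m$y0 + 16
    d <- (cx - cx[centre])^2 + (cy - cy[centre])^2
    oracle <- m$index[order(d, m$index)[1:k]]
    expect_setequal(s$index, oracle)
  }
})

test_that("subsample sizes honour round(fraction x N)", {
  m <- grid_map(5, 5, runif(25))
  for (f in c(2, 4, 6, 8, 10) / 15)
    expect_equal(nrow(draw_subsample(m, f, seed = 1)), round(f * 25))
  expect_error(draw_subsample(m, 1.2, seed = 1), "fraction")
})

test_that("the heterogeneity call uses a strict > threshold", {
  mk_result <- function(devs) {
    structure(tibble::tibble(fraction = 2 / 15, draw = seq_along(devs),
                             centre = 1L, subsample_cif = 0.5,
                             deviation = devs),
              whole_cif = 0.5, fractions = 2 / 15, draws = length(devs),
              seed = 1L, class = c("subsample_result", "tbl_df", "tbl", "data.frame"))
  }
  expect_equal(classify_heterogeneity(mk_result(c(0.05, 0.100)), 0.1),
               "homogeneous")   # exactly at threshold: not heterogeneous
  expect_equal(classify_heterogeneity(mk_result(c(0.05, 0.1001)), 0.1),
               "heterogeneous")
})

test_that("a half-and-half map is heterogeneous; deviations reach 0.5", {
  m <- half_half_map()
  r <- deviation_curve(m, draws = 20, seed = 7)
  expect_equal(classify_heterogeneity(r), "heterogeneous")
  # the smallest fraction admits deviations near 0.5 over centre choices
  best <- 0
  for (centre in seq_len(nrow(m))) {
    s <- draw_subsample(m, 2 / 15, centre = centre)
    best <- max(best, abs(mean(s$cif) - cif_aggregate(m)))
  }
  expect_gte(best, 0.45)
})

test_that("deviation curves are reproducible for a fixed seed", {
  m <- half_half_map()
  a <- deviation_curve(m, draws = 10, seed = 11)
  b <- deviation_curve(m, draws = 10, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- deviation_curve(m, draws = 10, seed = 12)
  expect_false(identical(a$centre, c2$centre))
})

test_that("cohort summaries aggregate per group and fraction", {
  uniform <- grid_map(5, 5, rep(0.3, 25))
  r1 <- deviation_curve(uniform, draws = 5, seed = 1)
  r2 <- deviation_curve(uniform, draws = 5, seed = 2)
  tab <- cohort_adequacy_summary(list(a = r1, b = r2))
  expect_true(all(tab$mean_max_deviation == 0))
  expect_true(all(tab$n_slides == 2))
  # a single slide's summary equals its own curve
  het <- deviation_curve(half_half_map(), draws = 10, seed = 3)
  solo <- cohort_adequacy_summary(list(x = het))
  expect_equal(solo$mean_max_deviation,
               max_deviation_by_fraction(het)$max_deviation)
  expect_error(cohort_adequacy_summary(list()), "empty")
})

test_that("subsample JSON records the call and the curve", {
  m <- half_half_map()
  r <- deviation_curve(m, draws = 8, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_subsample_json(r, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$classification, classify_heterogeneity(r))
  expect_equal(x$whole_cif, cif_aggregate(m))
  expect_equal(nrow(x$draws_detail), nrow(r))
})
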