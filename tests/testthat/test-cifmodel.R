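# Ranking model: pair construction, training mechanics, calibration,
# metrics and heatmap rendering.

tiny_tiles <- function(values, side = 8) {
  lapply(values, function(v) array(clamp_val(v * 255), c(side, side, 3)))
}
clamp_val <- function(x) pmin(pmax(x, 0), 255)

test_that("training pairs respect the label-gap rule", {
  p <- make_training_pairs(c(0.1, 0.9), delta = 0.2)
  expect_equal(nrow(p), 1)
  expect_equal(p$hi, 2)
  expect_equal(p$lo, 1)
  expect_error(make_training_pairs(rep(0.4, 5), delta = 0.1), "lower")
  expect_error(make_training_pairs(0.5, delta = 0.1), "two")
  # exhaustive count matches an O(n^2) loop
  set.seed(8); labels <- runif(100)
  cnt <- 0
  for (i in 1:100) for (j in 1:100)
    if (labels[i] - labels[j] >= 0.3) cnt <- cnt + 1
  expect_equal(nrow(make_training_pairs(labels, delta = 0.3)), cnt)
  # sampling is deterministic per seed
  a <- make_training_pairs(labels, 0.3, n_pairs = 50, seed = 4)
  b <- make_training_pairs(labels, 0.3, n_pairs = 50, seed = 4)
  expect_identical(a, b)
})

test_that("the loss decreases on a single repeated pair", {
  set.seed(12)
  lo_tile <- array(sample(80:120, 192, TRUE), c(8, 8, 3))
  hi_tile <- array(sample(160:220, 192, TRUE), c(8, 8, 3))
  m <- train_ranking_model(list(hi_tile, lo_tile), c(0.9, 0.1),
                           ranking_config(epochs = 8, equalize = FALSE,
                                          input_px = 2, seed = 1))
  h <- tidy(m)$loss
  expect_lt(h[8], h[1])
})

test_that("training is reproducible and calibration pins the endpoints", {
  set.seed(2)
  labels <- runif(30)
  tiles <- tiny_tiles(labels + rnorm(30, 0, 0.02))
  cfg <- ranking_config(epochs = 15, input_px = 2, equalize = FALSE, seed = 6)
  m1 <- train_ranking_model(tiles, labels, cfg)
  m2 <- train_ranking_model(tiles, labels, cfg)
  expect_identical(m1$par, m2$par)
  expect_identical(tidy(m1), tidy(m2))
  # predicting the training set reaches both calibration endpoints
  p <- predict_cif(m1, tiles)
  expect_equal(min(p$cif), 0)
  expect_equal(max(p$cif), 1)
  expect_true(all(p$cif >= 0 & p$cif <= 1))
  # glance carries the calibration range
  g <- glance(m1)
  expect_equal(g$calibration_lo, unname(m1$calibration["lo"]))
  # an uncalibrated model refuses to predict
  m1$calibration <- NULL
  expect_error(predict_cif(m1, tiles), "calibration")
})

test_that("pairwise accuracy matches trivia and an exhaustive oracle", {
  labels <- seq(0, 1, length.out = 20)
  expect_equal(pairwise_prediction_accuracy(labels, labels, 0.1), 1)
  expect_equal(pairwise_prediction_accuracy(rev(labels), labels, 0.1), 0)
  set.seed(14)
  pred <- runif(40); truth <- runif(40)
  conc <- 0; tot <- 0
  for (i in 1:40) for (j in 1:40) {
    if (truth[i] - truth[j] >= 0.1) {
      tot <- tot + 1
      if (pred[i] > pred[j]) conc <- conc + 1
    }
  }
  expect_equal(pairwise_prediction_accuracy(pred, truth, 0.1), conc / tot)
  expect_error(pairwise_prediction_accuracy(1, 0.5, 0.1), "delta")
})

test_that("mean CIF difference matches direct recomputation", {
  set.seed(3)
  a <- cif_map(0:19, rep(0, 20), rep(0, 20), runif(20), 64L)
  expect_equal(mean_cif_difference(a, a)$mean_abs_diff, 0)
  # constant offset (chosen so no clipping occurs)
  a2 <- a; a2$cif <- runif(20, 0, 0.8); b2 <- a2; b2$cif <- a2$cif + 0.1
  d <- mean_cif_difference(a2, b2)
  expect_equal(d$mean_abs_diff, 0.1)
  expect_equal(d$sd_abs_diff, 0, tolerance = 1e-12)
  # random maps vs direct loop
  c2 <- a; c2$cif <- runif(20)
  expect_equal(mean_cif_difference(a, c2)$mean_abs_diff,
               mean(abs(a$cif - c2$cif)))
  # disjoint tile sets error
  e <- cif_map(100:119, rep(0, 20), rep(0, 20), runif(20), 64L)
  expect_error(mean_cif_difference(a, e), "share")
})

test_that("heatmap rendering paints exact palette colours per tile", {
  img <- array(245, c(8, 8, 3))
  pal <- hcl.colors(256, "viridis")
  pal_rgb <- col2rgb(pal)
  map <- cif_map(0:3, c(0, 4, 0, 4), c(0, 0, 4, 4), c(0, 1, 1, 0), 4L)
  hm <- render_heatmap(map, img, alpha = 1, palette = pal)
  expect_equal(hm[1, 1, ], unname(pal_rgb[, 1]))      # cif 0 -> lowest colour
  expect_equal(hm[1, 5, ], unname(pal_rgb[, 256]))    # cif 1 -> highest colour
  expect_equal(hm[5, 1, ], unname(pal_rgb[, 256]))
  expect_equal(hm[5, 5, ], unname(pal_rgb[, 1]))
  # uniform maps give a single colour field
  u <- cif_map(0:3, c(0, 4, 0, 4), c(0, 0, 4, 4), rep(0, 4), 4L)
  hu <- render_heatmap(u, img, alpha = 1, palette = pal)
  expect_true(all(hu[, , 1] == pal_rgb[1, 1]))
  # geometry mismatch errors
  big <- cif_map(0L, 6L, 6L, 0.5, 4L)
  expect_error(render_heatmap(big, img), "geometry")
})

test_that("cif maps aggregate by the arithmetic mean and round-trip CSV", {
  m <- cif_map(0:5, rep(0, 6), rep(0, 6), seq(0, 1, length.out = 6), 32L)
  expect_equal(cif_aggregate(m), mean(m$cif))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cif_map_csv(m, path)
  m2 <- read_cif_map_csv(path)
  expect_equal(m2$cif, m$cif)
  expect_error(cif_map(0L, 0L, 0L, 1.2, 32L), "\\[0, 1\\]")
})
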