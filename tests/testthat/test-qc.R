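# Slide-level QC: dominant colour, CIELAB conversion, colour variation,
# bone area and analysable tile counts.

solid <- function(h, w, colour) {
  img <- array(0, c(h, w, 3))
  for (c in 1:3) img[, , c] <- colour[c]
  img
}

test_that("dominant colour: uniform, majority and empty-mask cases", {
  magenta <- c(200, 40, 180)
  img <- solid(20, 20, magenta)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(unname(dominant_colour(img, mask)), magenta)
  # 70% colour A / 30% colour B -> A
  img2 <- solid(20, 20, c(210, 160, 190))
  img2[1:6, , ] <- rep(c(80, 90, 100), each = 120)
  expect_equal(unname(dominant_colour(img2, mask)), c(210, 160, 190))
  expect_error(dominant_colour(img, matrix(FALSE, 20, 20)), "empty")
})

test_that("CIELAB conversion matches the standard formulas", {
  w <- rgb_to_cielab(c(255, 255, 255))
  expect_equal(unname(w[1]), 100, tolerance = 1e-6)
  expect_lte(abs(w[2]), 0.01)
  expect_lte(abs(w[3]), 0.01)
  expect_equal(unname(rgb_to_cielab(c(0, 0, 0))), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(rgb_to_cielab(c(128, 128, 128))),
               unname(lab_oracle(128, 128, 128)), tolerance = 1e-6)
  # vectorised variant agrees with the scalar oracle over a colour grid
  g <- as.matrix(expand.grid(r = seq(0, 255, length.out = 5),
                             g = seq(0, 255, length.out = 5),
                             b = seq(0, 255, length.out = 5)))
  got <- rgb_to_cielab(g)
  want <- t(apply(g, 1, function(p) lab_oracle(p[1], p[2], p[3])))
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
  # L* spans [0, 100] up to the sRGB matrix's last-digit rounding
  expect_true(all(got[, 1] >= -1e-4 & got[, 1] <= 100 + 1e-4))
})

test_that("Lab -> RGB -> Lab round-trips within half a unit in gamut", {
  g <- expand.grid(r = seq(20, 235, length.out = 5),
                   g = seq(20, 235, length.out = 5),
                   b = seq(20, 235, length.out = 5))
  lab <- rgb_to_cielab(as.matrix(g))
  for (i in seq(1, nrow(lab), by = 7)) {
    rgb_back <- lab_to_rgb_oracle(lab[i, 1], lab[i, 2], lab[i, 3])
    lab_back <- rgb_to_cielab(rgb_back)
    expect_lte(max(abs(lab_back - lab[i, ])), 0.5)
  }
})

test_that("colour variation: zero-variance, textbook values and dispersion", {
  same <- tibble::tibble(arm = rep(c("he", "ret"), each = 3),
                         r = 200, g = 150, b = 180)
  cv <- colour_variation(same, n_boot = 50, seed = 1)
  expect_true(all(cv$by_channel$variance == 0))
  # hand-entered three-slide cohort matches var()
  cols <- tibble::tibble(arm = "he",
                         r = c(200, 210, 190), g = c(150, 140, 160),
                         b = c(180, 185, 175))
  cols2 <- dplyr::bind_rows(cols, tibble::tibble(arm = "ret",
                                                 r = c(100, 180, 240),
                                                 g = c(90, 150, 230),
                                                 b = c(80, 160, 250)))
  cv2 <- colour_variation(cols2, n_boot = 50, seed = 1)
  rgb_he <- cv2$by_channel[cv2$by_channel$arm == "he" &
                           cv2$by_channel$space == "RGB", ]
  expect_equal(rgb_he$variance[rgb_he$channel == "r"], var(c(200, 210, 190)))
  # the wildly varying arm has the larger trace in both spaces
  disp <- cv2$dispersion
  expect_gt(disp$trace[disp$arm == "ret" & disp$space == "RGB"],
            disp$trace[disp$arm == "he" & disp$space == "RGB"])
  expect_gt(disp$trace[disp$arm == "ret" & disp$space == "LAB"],
            disp$trace[disp$arm == "he" & disp$space == "LAB"])
  expect_error(colour_variation(tibble::tibble(arm = c("a", "b"), r = 1,
                                               g = 1, b = 1)), "2 slides")
})

test_that("bone area follows pixel count x (mpp/1000)^2 exactly", {
  expect_equal(bone_area(matrix(FALSE, 50, 50), 0.25), 0)
  expect_equal(bone_area(matrix(TRUE, 100, 100), 10), 1)
  m <- matrix(FALSE, 80, 80); m[10:39, 20:49] <- TRUE
  expect_equal(bone_area(m, 0.5), 900 * (0.5 / 1000)^2)
  # quadratic scaling in mpp
  expect_equal(bone_area(m, 1) * 4, bone_area(m, 2))
  expect_error(bone_area(m, 0), "mpp")
})

test_that("analysable tile counting with and without an annotation mask", {
  tab <- tibble::tibble(index = 0:11, x0 = rep(c(0, 64, 128, 192), 3),
                        y0 = rep(c(0, 64, 128), each = 4), tile_size = 64L,
                        analysable = rep(c(TRUE, TRUE, FALSE), 4))
  expect_equal(analysable_tile_count(tab), 8)
  none <- tab; none$analysable <- FALSE
  expect_equal(analysable_tile_count(none), 0)
  # annotation over the left half of a fully analysable 4 x 4 grid
  grid <- grid_tile_table(4, 4, 64)
  grid$analysable <- TRUE
  ann <- cbind(matrix(TRUE, 256, 128), matrix(FALSE, 256, 128))
  expect_equal(analysable_tile_count(grid, ann), 8)
  bad <- grid; bad$analysable <- NA
  expect_error(analysable_tile_count(bad), "populated")
})

test_that("per-slide QC reports and paired comparisons assemble", {
  pair <- small_pair()
  tt <- extract_tiles(tissue_mask = pair$tissue_mask, tile_size = 64,
                      fat_mask = pair$fat_mask, bone_mask = pair$bone_mask)
  rep <- qc_report(pair$he_image, pair$tissue_mask, pair$bone_mask, tt,
                   mpp = pair$spec$mpp, id = "s1")
  expect_equal(nrow(rep), 1)
  expect_gte(rep$bone_area_mm2, 0)
  expect_true(rep$L >= 0 && rep$L <= 100)
  expect_equal(rep$analysable_tiles, analysable_tile_count(tt))
  out <- paired_qc_test(c(2.5, 3.1, 2.8, 3.4), c(2.15, 2.6, 2.9, 3.0))
  expect_true(out$p_value > 0 && out$p_value <= 1)
})
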