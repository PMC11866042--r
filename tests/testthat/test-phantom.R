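# Phantom generator: determinism, monotone rendering, ground-truth labels,
# bone loss and the known misalignment.

stroke_count <- function(pair) {
  # exact stroke-colour match; valid while stain drift is zero
  img <- pair$he_image
  sum(img[, , 1] == 150 & img[, , 2] == 60 & img[, , 3] == 110)
}

test_that("generation is bit-identical for a fixed spec and seed", {
  sp <- phantom_spec(width_px = 160, height_px = 160, mpp = 1,
                     fibrosis_field = list(type = "random", mean = 0.5,
                                           amplitude = 0.3,
                                           correlation_length_px = 48),
                     n_bone_blobs = 1, fat_fraction = 0.05,
                     stain_drift_sd = 4, bone_loss_fraction = 0.2, seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$he_image, b$he_image)
  expect_identical(a$reticulin_image, b$reticulin_image)
  expect_identical(a$fibrosis_field, b$fibrosis_field)
  expect_identical(a$true_affine$matrix, b$true_affine$matrix)
})

test_that("zero severity renders no fibre strokes and all-zero labels", {
  pair <- flat_pair(value = 0, seed = 9)
  expect_equal(stroke_count(pair), 0)
  tt <- extract_tiles(tissue_mask = pair$tissue_mask, tile_size = 64,
                      min_tissue_fraction = 0.5)
  labs <- ground_truth_tile_labels(pair, tt)
  expect_true(all(labs$label == 0))
})

test_that("fibre density is monotone in severity at a fixed seed", {
  counts <- vapply(c(0.2, 0.5, 0.9),
                   function(s) stroke_count(flat_pair(value = s, seed = 3)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])  # strictly more texture across the range
})

test_that("identity misalignment yields the identity transform", {
  pair <- flat_pair(value = 0.4, seed = 5)
  expect_equal(pair$true_affine$matrix, cbind(diag(2), c(0, 0)),
               tolerance = 1e-12)
  # and the two frames then share the tissue mask exactly
  expect_identical(pair$reticulin_tissue_mask, pair$tissue_mask)
})

test_that("true_affine matches the closed-form rotation + translation", {
  pair <- small_pair()
  centre <- c((320 - 1) / 2, (320 - 1) / 2)
  th <- 3 * pi / 180
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  oracle <- cbind(rot, centre - rot %*% centre + c(12, -7))
  expect_equal(pair$true_affine$matrix, oracle, tolerance = 1e-12)
})

test_that("tile labels equal footprint means of the latent field", {
  # constant field
  pair <- flat_pair(value = 0.7, seed = 3)
  tt <- grid_tile_table(3, 3, 64)
  expect_true(all(ground_truth_tile_labels(pair, tt)$label == 0.7))
  # half-and-half field, tile straddling the boundary evenly
  field <- cbind(matrix(0, 64, 32), matrix(1, 64, 32))
  lab <- ground_truth_tile_labels(field_pair(field),
                                  tibble::tibble(index = 0L, x0 = 16L, y0 = 16L,
                                                 tile_size = 32L))
  expect_equal(lab$label, 0.5)
  # smoothed random field vs brute-force pixel loop
  pair2 <- small_pair()
  x0 <- 96L; y0 <- 128L; t <- 64L
  acc <- 0
  for (i in seq_len(t)) for (j in seq_len(t))
    acc <- acc + pair2$fibrosis_field[y0 + i, x0 + j]
  lab2 <- ground_truth_tile_labels(
    pair2, tibble::tibble(index = 0L, x0 = x0, y0 = y0, tile_size = t))
  expect_equal(lab2$label, acc / t^2, tolerance = 1e-12)
  # out-of-raster tile errors with the tile index
  expect_error(ground_truth_tile_labels(
    pair2, tibble::tibble(index = 41L, x0 = 300L, y0 = 0L, tile_size = 64L)),
    "41")
})

test_that("pseudo-reticulin bone area is (1 - loss) of the H&E bone area", {
  pair <- small_pair()  # bone_loss_fraction 0.3, rotation 3 deg
  ratio <- sum(pair$reticulin_bone_mask) / sum(pair$bone_mask)
  expect_equal(ratio, 0.7, tolerance = 0.02)
})

test_that("masks are disjoint and the warped frames agree (IoU >= 0.95)", {
  pair <- small_pair()
  expect_equal(sum(pair$bone_mask & pair$fat_mask), 0)
  expect_true(all(pair$fat_mask <= pair$tissue_mask))
  warped <- hecif:::warp_matrix(pair$reticulin_tissue_mask * 1,
                                pair$true_affine, dim(pair$tissue_mask),
                                interp = "nearest") > 0.5
  iou <- sum(warped & pair$tissue_mask) / sum(warped | pair$tissue_mask)
  expect_gte(iou, 0.95)
})

test_that("stain drift shifts both renderings by the recorded amounts", {
  sp0 <- phantom_spec(width_px = 160, height_px = 160, mpp = 1,
                      fibrosis_field = list(type = "constant", value = 0.3),
                      n_bone_blobs = 0, fat_fraction = 0,
                      stain_drift_sd = 0, seed = 13)
  sp1 <- sp0; sp1$stain_drift_sd <- 8
  a <- generate_phantom(sp0); b <- generate_phantom(sp1)
  shift <- b$stain_shift$he
  expect_false(all(shift == 0))
  # interior tissue pixels move by exactly the recorded (rounded) shift
  idx <- which(a$tissue_mask & !a$fat_mask)[100]
  for (c in 1:3)
    expect_equal(b$he_image[, , c][idx] - a$he_image[, , c][idx],
                 round(shift[c]))
})

test_that("invalid specs and off-canvas misalignments are rejected", {
  expect_error(phantom_spec(width_px = 8, height_px = 8), "32")
  expect_error(phantom_spec(fat_fraction = 1.2), "fat_fraction")
  expect_error(phantom_spec(fibrosis_field = list(type = "constant", value = 2)),
               "\\[0, 1\\]")
  sp <- phantom_spec(width_px = 160, height_px = 160,
                     misalignment = list(rotation_deg = 0,
                                         translation_px = c(5000, 5000),
                                         scale = 1), seed = 2)
  expect_error(generate_phantom(sp), "off-canvas")
})

test_that("write_phantom emits readable rasters and sidecar", {
  dir <- withr::local_tempdir()
  pair <- flat_pair(value = 0.4, seed = 5)
  paths <- write_phantom(pair, dir, "px")
  expect_identical(read_image_png(paths$he), pair$he_image)
  expect_identical(read_mask_png(paths$tissue_mask), pair$tissue_mask)
  field <- read_field_tiff(paths$field)
  expect_equal(field, pair$fibrosis_field, tolerance = 1e-6)
  side <- jsonlite::read_json(paths$sidecar, simplifyVector = TRUE)
  expect_equal(side$true_affine, pair$true_affine$matrix, tolerance = 1e-9)
})
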