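# Internal raster and RNG helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All seeded public functions funnel through this
# so that they neither depend on nor disturb the global RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

assert_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    abort(sprintf("`%s` must be an RGB array with dim [height, width, 3]", arg))
  if (any(dim(image)[1:2] == 0L))
    abort(sprintf("`%s` is empty (zero-sized dimension)", arg))
  invisible(image)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) abort(sprintf("`%s` must be a matrix", arg))
  invisible(mask)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 8-bit quantisation of a numeric array.
as_uint8 <- function(x) {
  x <- round(clamp(x, 0, 255))
  storage.mode(x) <- "integer"
  x
}

# Bilinear sampling of a single-channel matrix at fractional 0-based pixel
# coordinates (x = column, y = row). Out-of-bounds samples return `fill`.
sample_bilinear <- function(mat, x, y, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- rep(fill, length(x))
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  # clamp the +1 neighbour at the border so edge pixels sample themselves
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  i00 <- y0 + 1 + x0 * h; i10 <- y0 + 1 + x1 * h
  i01 <- y1 + 1 + x0 * h; i11 <- y1 + 1 + x1 * h
  v <- (1 - fx[ok]) * (1 - fy[ok]) * mat[i00[ok]] + fx[ok] * (1 - fy[ok]) * mat[i10[ok]] +
    (1 - fx[ok]) * fy[ok] * mat[i01[ok]] + fx[ok] * fy[ok] * mat[i11[ok]]
  out[ok] <- v
  out
}

# Nearest-neighbour sampling of a matrix at 0-based coordinates.
sample_nearest <- function(mat, x, y, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  xi <- round(x); yi <- round(y)
  out <- rep(fill, length(x))
  ok <- xi >= 0 & yi >= 0 & xi < w & yi < h
  out[ok] <- mat[yi[ok] + 1 + xi[ok] * h]
  out
}

# Bilinear upsampling of a coarse matrix onto an h x w grid; used by the
# phantom's smooth latent field.
upsample_bilinear <- function(coarse, h, w) {
  ch <- nrow(coarse); cw <- ncol(coarse)
  ys <- if (ch == 1) rep(0, h) else (seq_len(h) - 1) / (h - 1) * (ch - 1)
  xs <- if (cw == 1) rep(0, w) else (seq_len(w) - 1) / (w - 1) * (cw - 1)
  grid_x <- rep(xs, each = h)
  grid_y <- rep(ys, times = w)
  matrix(sample_bilinear(coarse, grid_x, grid_y), nrow = h, ncol = w)
}

# Sum of a matrix over the half-open tile [y0, y0+t) x [x0, x0+t), 0-based.
tile_sum <- function(mat, x0, y0, t) {
  sum(mat[(y0 + 1):(y0 + t), (x0 + 1):(x0 + t)])
}

# Morphology on logical matrices via EBImage (odd brush size, disc).
ebi_erode <- function(mask, size = 5L) {
  EBImage::erode(mask * 1, EBImage::makeBrush(size, "disc")) > 0.5
}

ebi_close <- function(mask, size = 5L) {
  EBImage::closing(mask * 1, EBImage::makeBrush(size, "disc")) > 0.5
}

# Paint a set of 0-based (x, y) pixel coordinates in each channel of `img`
# with `colour` (length 3), returning the modified array.
paint_pixels <- function(img, x, y, colour) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ok <- x >= 0 & x < w & y >= 0 & y < h
  if (!any(ok)) return(img)
  idx <- y[ok] + 1 + x[ok] * h
  n <- h * w
  for (c in 1:3) img[idx + (c - 1) * n] <- colour[c]
  img
}
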