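# Channel-wise histogram equalisation.
#
# Non-uniform staining shifts and compresses channel histograms between
# slides and scanners; equalising each channel against its own cumulative
# distribution removes global intensity differences before tiles reach the
# ranking model. The plain global form is used (not CLAHE): statistics are
# computed over the whole input raster.

#' Channel-wise histogram equalisation of an 8-bit RGB image
#'
#' Each channel is remapped by its own cumulative distribution to span
#' 0-255: `eq(v) = round(255 * (cdf(v) - cdf_min) / (n - cdf_min))`, where
#' `cdf_min` is the CDF at the lowest occupied level. The map is monotone,
#' so within-channel rank order is preserved, and it is invariant to any
#' global additive shift that does not clip. A constant channel maps to
#' mid-scale 128.
#'
#' @param image 8-bit RGB array (values 0-255).
#' @return Equalised RGB array, same shape, integer values 0-255.
#' @export
equalize_channels <- function(image) {
  assert_image(image)
  out <- image
  for (c in 1:3) out[, , c] <- equalize_one(image[, , c])
  as_uint8(out)
}

equalize_one <- function(ch) {
  v <- as.integer(round(clamp(ch, 0, 255)))
  n <- length(v)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (cdf_min == n) return(array(128L, dim(ch)))  # constant channel
  lut <- as.integer(round(255 * (cdf - cdf_min) / (n - cdf_min)))
  lut[lut < 0L] <- 0L
  array(lut[v + 1L], dim(ch))
}
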