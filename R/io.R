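# Raster I/O: 8-bit RGB images and binary masks as PNG, float rasters as
# 32-bit TIFF. All arrays follow the package convention [row, column,
# channel] with values 0-255 for images.

#' Read and write 8-bit RGB images as PNG
#'
#' @param image RGB array with values 0-255.
#' @param path File path.
#' @return `read_image_png` returns the RGB array (0-255).
#' @export
write_image_png <- function(image, path) {
  assert_image(image)
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  as_uint8(x * 255)
}

#' Read and write binary masks as single-channel PNG
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `read_mask_png` returns the logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' Read a 32-bit float raster written by [write_phantom()]
#'
#' @param path TIFF path.
#' @return Numeric matrix.
#' @export
read_field_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}
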