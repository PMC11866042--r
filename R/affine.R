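# Planar affine transforms between slide pixel frames.
#
# A transform maps source (reticulin-frame) pixel coordinates to destination
# (H&E-frame) pixel coordinates: p_dst = A %*% p_src + t, stored as the 2x3
# matrix [[a, b, tx], [c, d, ty]]. Coordinates are 0-based with x = column
# and y = row.

#' Create an affine transform from a 2x3 matrix
#'
#' @param m A 2x3 numeric matrix `[[a, b, tx], [c, d, ty]]` mapping source
#'   pixel coordinates `(x, y)` to destination coordinates.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 3L)) || !is.numeric(m) || any(!is.finite(m)))
    abort("an affine transform is a finite 2x3 numeric matrix")
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(det) <= 1e-9)
    abort("affine linear part is singular (|det| <= 1e-9)")
  structure(list(matrix = unname(m)), class = "affine_transform")
}

#' Build an affine transform from rotation, scale and translation
#'
#' The transform rotates by `rotation_deg` (counter-clockwise in the
#' `x`-right / `y`-down pixel frame) and scales by `scale` about `centre`,
#' then translates by `translation` pixels.
#'
#' @param rotation_deg Rotation in degrees.
#' @param translation Length-2 numeric, `(tx, ty)` in pixels.
#' @param scale Isotropic scale factor (> 0).
#' @param centre Length-2 numeric, centre of rotation/scaling in source
#'   pixel coordinates.
#' @return An `affine_transform`.
#' @export
affine_from_params <- function(rotation_deg = 0, translation = c(0, 0),
                               scale = 1, centre = c(0, 0)) {
  stopifnot(length(translation) == 2L, length(centre) == 2L, scale > 0)
  th <- rotation_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) * scale
  t <- c(centre[1], centre[2]) - rot %*% centre + translation
  affine_transform(cbind(rot, t))
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(round(x$matrix, 6))
  p <- affine_params(x)
  cat(sprintf("rotation %.3f deg, scale %.4f, translation (%.2f, %.2f)\n",
              p["rotation_deg"], p["scale"], p["tx"], p["ty"]))
  invisible(x)
}

#' Decompose an affine transform into rotation, scale and translation
#'
#' Returns the rotation angle (degrees), the mean isotropic scale of the
#' linear part, and the raw translation column. For similarity transforms
#' the decomposition is exact.
#'
#' @param t An `affine_transform`.
#' @return Named numeric vector `rotation_deg`, `scale`, `tx`, `ty`.
#' @export
affine_params <- function(t) {
  m <- t$matrix
  sc <- sqrt(abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]))
  c(rotation_deg = atan2(m[2, 1], m[1, 1]) * 180 / pi,
    scale = sc, tx = m[1, 3], ty = m[2, 3])
}

#' Compose two affine transforms
#'
#' `affine_compose(b, a)` returns the transform applying `a` first, then `b`.
#'
#' @param b,a `affine_transform` objects.
#' @return The composed `affine_transform`.
#' @export
affine_compose <- function(b, a) {
  bl <- b$matrix[, 1:2]; al <- a$matrix[, 1:2]
  affine_transform(cbind(bl %*% al, bl %*% a$matrix[, 3] + b$matrix[, 3]))
}

#' Invert an affine transform
#'
#' @param t An `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
affine_invert <- function(t) {
  a <- t$matrix[, 1:2]
  ai <- solve(a)
  affine_transform(cbind(ai, -ai %*% t$matrix[, 3]))
}

#' Apply an affine transform to point coordinates
#'
#' @param t An `affine_transform`.
#' @param points A data frame or matrix with columns `x`, `y` (0-based pixel
#'   coordinates), or a length-2 numeric vector.
#' @return A tibble with transformed `x`, `y` columns (or a length-2 vector
#'   when the input was one).
#' @export
map_coords <- function(t, points) {
  stopifnot(inherits(t, "affine_transform"))
  single <- is.numeric(points) && is.null(dim(points)) && length(points) == 2L
  if (single) points <- matrix(points, 1, 2, dimnames = list(NULL, c("x", "y")))
  if (is.data.frame(points)) pm <- cbind(points$x, points$y)
  else pm <- as.matrix(points)[, 1:2, drop = FALSE]
  if (any(!is.finite(pm))) abort("coordinates must be finite")
  m <- t$matrix
  out <- cbind(m[1, 1] * pm[, 1] + m[1, 2] * pm[, 2] + m[1, 3],
               m[2, 1] * pm[, 1] + m[2, 2] * pm[, 2] + m[2, 3])
  if (single) return(c(x = out[1, 1], y = out[1, 2]))
  tibble(x = out[, 1], y = out[, 2])
}

# Warp a matrix (mask or channel) into the destination frame of `t`:
# out[p] = mat[t^{-1}(p)]. `t` maps mat's frame -> output frame.
warp_matrix <- function(mat, t, out_dim = dim(mat),
                        interp = c("nearest", "bilinear"), fill = 0) {
  interp <- match.arg(interp)
  inv <- affine_invert(t)$matrix
  h <- out_dim[1]; w <- out_dim[2]
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  sx <- inv[1, 1] * gx + inv[1, 2] * gy + inv[1, 3]
  sy <- inv[2, 1] * gx + inv[2, 2] * gy + inv[2, 3]
  v <- if (interp == "nearest") sample_nearest(mat, sx, sy, fill)
       else sample_bilinear(mat, sx, sy, fill)
  matrix(v, nrow = h, ncol = w)
}

# Warp an RGB array channel-wise (see warp_matrix).
warp_image <- function(img, t, out_dim = dim(img)[1:2],
                       interp = "bilinear", fill = 255) {
  out <- array(0, c(out_dim, 3L))
  for (c in 1:3) out[, , c] <- warp_matrix(img[, , c], t, out_dim, interp, fill)
  out
}

#' Write / read an affine transform as JSON
#'
#' The JSON sidecar stores the 2x3 matrix row-major plus any diagnostics
#' attached by [estimate_affine()].
#'
#' @param t An `affine_transform`.
#' @param path File path.
#' @return `read_affine_json` returns the `affine_transform`.
#' @export
write_affine_json <- function(t, path) {
  stopifnot(inherits(t, "affine_transform"))
  x <- list(matrix = t$matrix)
  for (f in c("iou", "failed")) if (!is.null(attr(t, f))) x[[f]] <- attr(t, f)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  t <- affine_transform(x$matrix)
  if (!is.null(x$iou)) attr(t, "iou") <- x$iou
  if (!is.null(x$failed)) attr(t, "failed") <- x$failed
  t
}
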