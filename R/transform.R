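# 2D similarity transforms: isotropic scale + rotation about a pivot,
# followed by a translation.  A point p maps to
#   p' = s * R(theta) * (p - pivot) + pivot + translation
# with theta in degrees, positive from +x toward +y (i.e. visually clockwise
# in image coordinates where y points down).

#' Construct a similarity transform
#'
#' @param scale positive isotropic scale factor.
#' @param rotation_deg rotation angle in degrees (from +x toward +y).
#' @param translation numeric `(x, y)` translation in pixels.
#' @param pivot numeric `(x, y)` center of scaling/rotation.
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0,
                                 translation = c(0, 0), pivot = c(0, 0)) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop_strab("strab_input_error", "scale must be a positive finite number")
  structure(list(scale = as.numeric(scale),
                 rotation_deg = as.numeric(rotation_deg),
                 translation = assert_point(translation, "translation"),
                 pivot = assert_point(pivot, "pivot")),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> scale %.6g, rotation %.6g deg, translation (%.6g, %.6g), pivot (%.6g, %.6g)\n",
    x$scale, x$rotation_deg, x$translation[1], x$translation[2],
    x$pivot[1], x$pivot[2]))
  invisible(x)
}

# Affine form p' = A p + b
transform_affine <- function(tf) {
  th <- tf$rotation_deg * pi / 180
  A <- tf$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- tf$pivot + tf$translation - A %*% tf$pivot
  list(A = A, b = as.numeric(b))
}

#' Apply a similarity transform to points
#'
#' @param tf a `similarity_transform`.
#' @param points numeric `(x, y)` pair or an n x 2 matrix of points.
#' @return points of the same shape as the input.
#' @export
transform_points <- function(tf, points) {
  af <- transform_affine(tf)
  if (is.null(dim(points))) return(as.numeric(af$A %*% points + af$b))
  t(af$A %*% t(points) + af$b)
}

#' Invert a similarity transform
#' @param tf a `similarity_transform`.
#' @return the inverse transform (pivot at the origin).
#' @export
transform_invert <- function(tf) {
  af <- transform_affine(tf)
  Ai <- solve(af$A)
  similarity_transform(scale = 1 / tf$scale,
                       rotation_deg = -tf$rotation_deg,
                       translation = as.numeric(-Ai %*% af$b),
                       pivot = c(0, 0))
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#' @param first,second `similarity_transform` objects.
#' @return a `similarity_transform` (pivot at the origin).
#' @export
transform_compose <- function(first, second) {
  a1 <- transform_affine(first); a2 <- transform_affine(second)
  A <- a2$A %*% a1$A
  b <- as.numeric(a2$A %*% a1$b + a2$b)
  # recover scale/rotation from A (A = s R, R proper rotation)
  s <- sqrt(A[1, 1]^2 + A[2, 1]^2)
  th <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  similarity_transform(scale = s, rotation_deg = th, translation = b,
                       pivot = c(0, 0))
}

transform_is_identity <- function(tf, tol = 1e-9) {
  af <- transform_affine(tf)
  all(abs(af$A - diag(2)) < tol) && all(abs(af$b) < tol)
}

#' Warp a raster by a similarity transform
#'
#' The output raster lives in the target frame: output pixel `p` samples the
#' input at `T^-1(p)`.  Out-of-bounds source positions fill with background
#' (0/`FALSE`).  Applying the identity under nearest interpolation returns the
#' input unchanged.
#'
#' @param raster numeric or logical matrix.
#' @param tf a `similarity_transform` mapping input frame to output frame.
#' @param interp `"bilinear"` (images) or `"nearest"` (masks; keeps rasters
#'   binary).
#' @return matrix of the same shape and mode as the input.
#' @export
apply_transform <- function(raster, tf, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (!is.matrix(raster) || length(raster) == 0L)
    stop_strab("strab_input_error", "raster must be a nonempty matrix")
  if (!inherits(tf, "similarity_transform"))
    stop_strab("strab_input_error", "tf must be a similarity_transform")
  was_logical <- is.logical(raster)
  h <- nrow(raster); w <- ncol(raster)
  if (transform_is_identity(tf)) return(raster)
  af <- transform_affine(tf)
  Ai <- solve(af$A)
  g <- pixel_grid(c(h, w))
  sx <- Ai[1, 1] * (g$x - af$b[1]) + Ai[1, 2] * (g$y - af$b[2])
  sy <- Ai[2, 1] * (g$x - af$b[1]) + Ai[2, 2] * (g$y - af$b[2])
  vals <- as.numeric(raster)
  out <- numeric(h * w)
  if (interp == "nearest") {
    cx <- round(sx); cy <- round(sy)
    ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
    out[ok] <- vals[cy[ok] + cx[ok] * h + 1]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    # sample with zero fill outside [0, w) x [0, h)
    samp <- function(xx, yy) {
      v <- numeric(h * w)
      ok <- xx >= 0 & xx < w & yy >= 0 & yy < h
      v[ok] <- vals[yy[ok] + xx[ok] * h + 1]
      v
    }
    out <- (1 - fx) * (1 - fy) * samp(x0, y0) +
      fx * (1 - fy) * samp(x0 + 1, y0) +
      (1 - fx) * fy * samp(x0, y0 + 1) +
      fx * fy * samp(x0 + 1, y0 + 1)
  }
  res <- matrix(out, h, w)
  if (was_logical) res > 0.5 else res
}

#' Serialize a similarity transform to a plain list (for JSON)
#' @param tf a `similarity_transform`.
#' @return named list of scalar fields.
#' @export
transform_to_list <- function(tf) {
  list(scale = tf$scale, rotation_deg = tf$rotation_deg,
       translation = as.numeric(tf$translation),
       pivot = as.numeric(tf$pivot))
}
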