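# Raster primitives shared across modules.
#
# Coordinate convention (used everywhere in the package): pixel coordinates
# with origin at the top-left pixel center, x rightward (columns), y downward
# (rows), 0-based, subpixel positions as reals.  A matrix element M[r, c]
# (1-based R indexing) is the pixel at (x = c - 1, y = r - 1).  Masks are
# rasterized by a center-of-pixel inclusion test.

#' Pixel-center coordinate grids for a raster shape
#'
#' @param shape integer `(height, width)`.
#' @return list with `x` and `y` matrices of the given shape.
#' @keywords internal
pixel_grid <- function(shape) {
  h <- shape[1]; w <- shape[2]
  list(
    x = matrix(rep(0:(w - 1), each = h), h, w),
    y = matrix(rep(0:(h - 1), times = w), h, w)
  )
}

#' Coordinates of foreground pixels
#'
#' @param mask logical (or 0/1) matrix.
#' @return two-column matrix of (x, y) pixel-center coordinates, one row per
#'   foreground pixel, in column-major scan order.
#' @keywords internal
mask_points <- function(mask) {
  mask <- assert_mask(mask)
  idx <- which(mask)
  h <- nrow(mask)
  cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
}

#' Centroid of a binary mask
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return numeric `(x, y)`.
#' @export
mask_centroid <- function(mask) {
  pts <- mask_points(mask)
  if (nrow(pts) == 0L)
    stop_strab("strab_degenerate_mask", "centroid of an empty mask is undefined")
  c(x = mean(pts[, 1]), y = mean(pts[, 2]))
}

#' Rasterize a filled disk by center-of-pixel inclusion
#'
#' @param shape `(height, width)`.
#' @param center `(x, y)` disk center in pixel coordinates.
#' @param radius positive radius in pixels.
#' @return logical matrix.
#' @export
disk_mask <- function(shape, center, radius) {
  h <- shape[1]; w <- shape[2]
  dx2 <- ((0:(w - 1)) - center[1])^2
  dy2 <- ((0:(h - 1)) - center[2])^2
  outer(dy2, dx2, "+") <= radius^2
}

#' Label connected components of a binary mask
#'
#' Components use 8-connectivity (the package-wide convention for blob
#' masks).  Implemented as a pixel-adjacency graph over foreground pixels.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape: 0 for background, 1..k component
#'   labels ordered by decreasing pixel count (ties by first scan position).
#' @export
label_components <- function(mask) {
  mask <- assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  inmask <- logical(h * w)
  inmask[idx] <- TRUE
  r <- (idx - 1L) %% h
  cc <- (idx - 1L) %/% h
  # half the 8-neighbourhood; the other half is covered by symmetry
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    rn <- r + o[1]; cn <- cc + o[2]
    ok <- rn >= 0L & rn < h & cn >= 0L & cn < w
    nidx <- rn[ok] + cn[ok] * h + 1L
    keep <- inmask[nidx]
    from <- c(from, idx[ok][keep])
    to <- c(to, nidx[keep])
  }
  vmap <- integer(h * w)
  vmap[idx] <- seq_along(idx)
  g <- igraph::make_graph(edges = rbind(vmap[from], vmap[to]),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  ord <- order(-sizes, vapply(seq_along(sizes), function(k)
    min(which(comp$membership == k)), integer(1)))
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  lab[idx] <- relabel[comp$membership]
  lab
}

#' Outer boundary pixels of a mask
#'
#' A foreground pixel is boundary if any 4-neighbour is background or lies
#' outside the raster.
#'
#' @param mask logical matrix.
#' @return logical matrix marking boundary pixels.
#' @keywords internal
mask_boundary <- function(mask) {
  mask <- assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  mask & !interior
}

# PNG I/O ---------------------------------------------------------------

#' Read a binary mask from a single-channel PNG (nonzero = foreground)
#' @param path file path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  arr > 0
}

#' Write a binary mask as an 8-bit single-channel PNG
#' @param mask logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(assert_mask(mask) * 1.0, path)
  invisible(path)
}

#' Read a grayscale image from PNG
#'
#' RGB(A) inputs are converted to luminance; values are in `[0, 1]`.
#' @param path file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  to_gray(arr)
}

#' Write a grayscale image to PNG
#' @param image numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Convert a raster to single-channel grayscale
#' @param image matrix (returned as-is) or H x W x C array.
#' @return numeric matrix.
#' @keywords internal
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3L) {
    if (d[3] >= 3L)
      return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
    return(image[, , 1])
  }
  stop_strab("strab_input_error", "image must be a matrix or H x W x C array")
}
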