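# Landmark-based similarity registration of eccentric-gaze frames onto the
# primary-gaze frame.
#
# The landmarks are the innermost (nasal-most) points of the two sclera
# regions -- the most head-pose-stable features in the scene.  The segment
# joining them defines a reference line; matching its center, length and
# angle to the primary gaze's line fixes translation, isotropic scale and
# rotation.

#' Innermost (nasal-most) sclera points
#'
#' For the image-left eye this is the foreground pixel with maximal x; for
#' the image-right eye, minimal x (both point toward the facial midline).
#' Ties are broken by minimal y, then minimal x.
#'
#' With `refine = TRUE` the pixel landmark is refined to subpixel precision
#' as the centroid of the foreground pixels within 1.5 px of the extreme
#' x -- the tip neighborhood of the medial canthus.  Pixel-level landmarks
#' carry +/-0.5 px quantization noise in each coordinate, which is the
#' dominant error of the two-point similarity solve; the centroid is stable
#' to a fraction of a pixel.
#'
#' @param left_sclera,right_sclera logical masks of the two sclera
#'   components.
#' @param refine return subpixel-refined landmarks (default `FALSE`: the
#'   exact extreme pixel with the documented tie rule).
#' @return list with `left` and `right` `(x, y)` points.
#' @export
innermost_points <- function(left_sclera, right_sclera, refine = FALSE) {
  pick <- function(mask, inner = c("max_x", "min_x")) {
    inner <- match.arg(inner)
    pts <- mask_points(mask)
    if (nrow(pts) == 0L)
      stop_strab("strab_degenerate_mask", "empty sclera component")
    xs <- pts[, 1]
    xb <- if (inner == "max_x") max(xs) else min(xs)
    cand <- pts[xs == xb, , drop = FALSE]
    cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
    extreme <- as.numeric(cand[1, ])
    if (refine) {
      # centroid of the tip neighborhood around the extreme pixel; the tight
      # y-window keeps distant boundary pixels of the eyeball disk out when
      # camera roll moves the canthus tip off the horizontal
      tip <- pts[abs(xs - extreme[1]) <= 1.5 &
                   abs(pts[, 2] - extreme[2]) <= 2.5, , drop = FALSE]
      return(colMeans(tip))
    }
    extreme
  }
  list(left = pick(left_sclera, "max_x"), right = pick(right_sclera, "min_x"))
}

normalize_angle <- function(deg) {
  a <- (deg + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

#' Reference line between the two innermost sclera points
#'
#' @param p_left,p_right `(x, y)` points (image-left and image-right eye).
#' @return a `reference_line`: list with `center` (midpoint), `length`
#'   (Euclidean, px) and `angle_deg` (atan2 from `p_left` to `p_right`,
#'   normalized to `(-180, 180]`).
#' @export
reference_line <- function(p_left, p_right) {
  p_left <- assert_point(p_left, "p_left")
  p_right <- assert_point(p_right, "p_right")
  d <- p_right - p_left
  len <- sqrt(sum(d^2))
  if (len == 0)
    stop_strab("strab_degenerate_geometry", "reference points coincide")
  structure(list(center = (p_left + p_right) / 2, length = len,
                 angle_deg = normalize_angle(atan2(d[2], d[1]) * 180 / pi)),
            class = "reference_line")
}

line_endpoints <- function(line) {
  th <- line$angle_deg * pi / 180
  half <- line$length / 2 * c(cos(th), sin(th))
  list(p1 = line$center - half, p2 = line$center + half)
}

#' Solve the similarity transform aligning one reference line onto another
#'
#' Scale and rotation act about the moving line's center (the pivot), then a
#' translation moves that center onto the fixed line's center; the moving
#' line's endpoints land exactly on the fixed line's endpoints.
#'
#' @param moving,fixed `reference_line` objects (from the gaze being
#'   registered, and from the primary gaze).
#' @return a [similarity_transform()].
#' @export
solve_similarity <- function(moving, fixed) {
  for (ln in list(moving, fixed))
    if (!is.finite(ln$length) || ln$length <= 0)
      stop_strab("strab_degenerate_geometry", "reference line has zero length")
  similarity_transform(
    scale = fixed$length / moving$length,
    rotation_deg = normalize_angle(fixed$angle_deg - moving$angle_deg),
    translation = fixed$center - moving$center,
    pivot = moving$center
  )
}

#' Measure a scene's reference line from its sclera mask
#'
#' Splits the sclera mask into the two eye components, finds the innermost
#' points, and joins them.
#'
#' @param sclera_mask logical mask containing both sclera regions.
#' @param min_area minimum component area for [split_eyes()].
#' @param refine use subpixel landmark refinement (default `TRUE`; see
#'   [innermost_points()]).
#' @return a `reference_line`.
#' @export
scene_reference_line <- function(sclera_mask, min_area = 20, refine = TRUE) {
  comps <- split_eyes(sclera_mask, min_area)
  pts <- innermost_points(comps$left, comps$right, refine = refine)
  reference_line(pts$left, pts$right)
}

#' Register one gaze frame onto the primary frame
#'
#' Measures the scene's own reference line from its sclera mask, solves the
#' similarity transform onto `primary_line`, and applies it to the image
#' (bilinear) and all masks (nearest-neighbor).
#'
#' @param image numeric matrix (may be `NULL` if only masks are needed).
#' @param masks named list of logical masks; must include `sclera`.
#' @param primary_line the primary gaze's `reference_line`.
#' @param min_area minimum sclera component area.
#' @return list with `image`, `masks` (both registered), `transform`, and
#'   `line` (the scene's own pre-registration reference line).
#' @export
register_gaze <- function(image, masks, primary_line, min_area = 20) {
  if (is.null(masks$sclera))
    stop_strab("strab_input_error", "masks must include a 'sclera' mask")
  line <- scene_reference_line(masks$sclera, min_area)
  tf <- solve_similarity(line, primary_line)
  reg_masks <- lapply(masks, apply_transform, tf = tf, interp = "nearest")
  reg_image <- if (!is.null(image)) apply_transform(image, tf, "bilinear")
  list(image = reg_image, masks = reg_masks, transform = tf, line = line)
}
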