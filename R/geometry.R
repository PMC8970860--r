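# Limbus and sclera geometry: minimum enclosing circles, corneal reflex
# localization, direct least-squares ellipse fitting, and recovery of the
# limbus center in eccentric gazes by short-axis extension.

#' Construct a circle
#' @param center `(x, y)` point. @param radius positive radius (px).
#' @return a `circle` object.
#' @export
circle <- function(center, radius) {
  center <- assert_point(center, "center")
  if (!is.finite(radius) || radius < 0)
    stop_strab("strab_invalid_geometry", "radius must be non-negative")
  structure(list(center = center, radius = as.numeric(radius)), class = "circle")
}

circle_from_2 <- function(p, q) circle((p + q) / 2, sqrt(sum((p - q)^2)) / 2)

# Circumcircle of three points; falls back to the diametral circle of the
# farthest pair when (near-)collinear.
circle_from_3 <- function(p, q, r) {
  ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  span <- max(abs(c(ax - bx, ay - by, ax - cx, ay - cy, bx - cx, by - cy)), 1)
  if (abs(d) < 1e-12 * span^2) {
    pairs <- list(list(p, q), list(p, r), list(q, r))
    dist2 <- vapply(pairs, function(pr) sum((pr[[1]] - pr[[2]])^2), numeric(1))
    pr <- pairs[[which.max(dist2)]]
    return(circle_from_2(pr[[1]], pr[[2]]))
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(ux, uy)
  circle(ctr, sqrt(sum((p - ctr)^2)))
}

in_circle <- function(circ, p, tol) sum((p - circ$center)^2) <= (circ$radius + tol)^2

#' Minimum enclosing circle of a mask or point set
#'
#' The unique smallest circle containing all foreground pixel centers.
#' Points are first reduced to their convex hull, then Welzl's incremental
#' algorithm runs on the hull vertices (exact, deterministic).
#'
#' @param x logical mask, or an n x 2 matrix of `(x, y)` points.
#' @return a `circle`.
#' @export
min_enclosing_circle <- function(x) {
  pts <- if (is.matrix(x) && !is.logical(x)) x else mask_points(x)
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  n <- nrow(pts)
  if (n == 0L)
    stop_strab("strab_degenerate_mask", "minimum enclosing circle of an empty set")
  if (n == 1L) return(circle(as.numeric(pts[1, ]), 0))
  if (n > 3L) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
    n <- nrow(pts)
  }
  scale <- max(abs(pts), 1)
  tol <- 1e-10 * scale
  P <- lapply(seq_len(n), function(i) as.numeric(pts[i, ]))
  circ <- circle_from_2(P[[1]], P[[2]])
  if (n >= 3L) for (i in 3:n) {
    if (in_circle(circ, P[[i]], tol)) next
    circ <- circle_from_2(P[[1]], P[[i]])
    for (j in 2:(i - 1)) {
      if (in_circle(circ, P[[j]], tol)) next
      circ <- circle_from_2(P[[j]], P[[i]])
      for (k in 1:(j - 1)) {
        if (!in_circle(circ, P[[k]], tol))
          circ <- circle_from_3(P[[k]], P[[j]], P[[i]])
      }
    }
  }
  circ
}

#' Locate the corneal light reflex inside the limbus
#'
#' Restricts the image to limbus pixels, thresholds at `threshold_frac` of
#' the in-mask maximum intensity, keeps the largest connected bright
#' component (8-connectivity) and returns its intensity-weighted centroid.
#' If no in-mask pixel reaches `floor` (fraction of the dynamic range) a
#' no-reflex error is raised: a reflex must be present in the primary gaze.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param limbus_mask logical mask (single eye's limbus).
#' @param threshold_frac relative threshold on the in-mask maximum
#'   (default 0.9).
#' @param floor absolute brightness floor as a fraction of the dynamic range
#'   (default 0.8); prevents latching onto iris texture.
#' @return `(x, y)` reflex point.
#' @export
detect_corneal_reflex <- function(image, limbus_mask, threshold_frac = 0.9,
                                  floor = 0.8) {
  limbus_mask <- assert_mask(limbus_mask, "limbus_mask")
  img <- to_gray(image)
  if (!identical(dim(img), dim(limbus_mask)))
    stop_strab("strab_input_error", "image and limbus_mask shapes differ")
  if (!any(limbus_mask))
    stop_strab("strab_degenerate_mask", "empty limbus mask")
  mx <- max(img[limbus_mask])
  if (mx < floor)
    stop_strab("strab_no_reflex",
               "no corneal reflex: in-limbus maximum %.3f below floor %.3f", mx, floor)
  bright <- limbus_mask & img >= threshold_frac * mx
  lab <- label_components(bright)
  blob <- lab == 1L  # components are ordered by size
  w <- img[blob]
  pts <- mask_points(blob)
  c(x = sum(pts[, 1] * w) / sum(w), y = sum(pts[, 2] * w) / sum(w))
}

#' Model the sclera as a circle tied to the limbus radius
#'
#' Center is the center of the sclera component's minimum enclosing circle;
#' the radius is `ratio` x the limbus radius (2.5 in adults).
#'
#' @param sclera_component logical mask of one eye's sclera.
#' @param limbus_radius limbus radius in pixels.
#' @param ratio sclera/limbus radius ratio (default 2.5).
#' @return a `circle`.
#' @export
model_sclera <- function(sclera_component, limbus_radius, ratio = 2.5) {
  if (!is.finite(limbus_radius) || limbus_radius <= 0)
    stop_strab("strab_invalid_geometry", "limbus_radius must be positive")
  mec <- min_enclosing_circle(sclera_component)
  circle(mec$center, ratio * limbus_radius)
}

#' Direct least-squares ellipse fit to a mask's boundary
#'
#' Fits a conic constrained to an ellipse (Fitzgibbon's direct method in the
#' numerically stable Halir--Flusser formulation) to the outer boundary
#' pixels of the mask's foreground, after centering for conditioning.  For
#' mask input the fitted semi-axes are inflated by 0.5 px: the outermost
#' included pixel *center* along any ray lies on average half a pixel inside
#' the continuous outline, so the raw fit systematically underestimates both
#' axes by that amount.
#'
#' @param x logical mask, or an n x 2 matrix of boundary `(x, y)` points
#'   (no half-pixel compensation is applied to raw points).
#' @return an `ellipse_fit`: `center` `(x, y)`, `semi_major`, `semi_minor`
#'   (px), `orientation_deg` (major-axis direction from +x toward +y,
#'   normalized to `(-90, 90]`).
#' @export
fit_ellipse <- function(x) {
  from_mask <- !(is.matrix(x) && !is.logical(x))
  pts <- if (from_mask) mask_points(mask_boundary(x)) else x
  pts <- unique(pts)
  if (nrow(pts) < 5L)
    stop_strab("strab_degenerate_mask",
               "ellipse fit needs >= 5 boundary points, got %d", nrow(pts))
  mu <- colMeans(pts)
  xx <- pts[, 1] - mu[1]; yy <- pts[, 2] - mu[2]
  D1 <- cbind(xx^2, xx * yy, yy^2)
  D2 <- cbind(xx, yy, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop_strab("strab_degenerate_mask", "degenerate conic system"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  va <- Re(ev$vectors)
  cond <- 4 * va[1, ] * va[3, ] - va[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L)
    stop_strab("strab_degenerate_mask", "no elliptical solution for these points")
  a1 <- va[, ok[1]]
  coef <- c(a1, as.numeric(Tm %*% a1))  # A B C D E F in centered coords
  A <- coef[1]; B <- coef[2]; C <- coef[3]; D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- 4 * A * C - B^2
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # value of the quadratic form at the center
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values  # decreasing
  axes2 <- -Fc / lam
  if (any(axes2 <= 0) || any(!is.finite(axes2)))
    stop_strab("strab_degenerate_mask", "degenerate conic (not an ellipse)")
  semi <- sqrt(axes2)  # lam decreasing => semi increasing? no: -Fc/lam
  ord <- order(-semi)
  major_vec <- eq$vectors[, ord[1]]
  orientation <- atan2(major_vec[2], major_vec[1]) * 180 / pi
  orientation <- ((orientation + 90) %% 180) - 90
  if (orientation == -90) orientation <- 90
  pad <- if (from_mask) 0.5 else 0  # half-pixel rasterization compensation
  structure(list(center = c(x = cx + mu[1], y = cy + mu[2]),
                 semi_major = semi[ord[1]] + pad, semi_minor = semi[ord[2]] + pad,
                 orientation_deg = orientation),
            class = "ellipse_fit")
}

#' Map an ellipse fit through a similarity transform
#'
#' A similarity transform commutes with ellipse fitting: the best-fit
#' ellipse of a transformed point set is the transformed ellipse.  Fitting
#' in a mask's native frame and mapping the fit avoids the aliasing noise
#' of fitting on a nearest-neighbor-resampled mask.
#'
#' @param fit an `ellipse_fit`.
#' @param tf a [similarity_transform()].
#' @return the transformed `ellipse_fit`.
#' @export
transform_ellipse <- function(fit, tf) {
  orientation <- fit$orientation_deg + tf$rotation_deg
  orientation <- ((orientation + 90) %% 180) - 90
  if (orientation == -90) orientation <- 90
  structure(list(center = transform_points(tf, fit$center),
                 semi_major = tf$scale * fit$semi_major,
                 semi_minor = tf$scale * fit$semi_minor,
                 orientation_deg = orientation),
            class = "ellipse_fit")
}

#' Recover the eccentric-gaze limbus center from an ellipse fit
#'
#' When the fitted limbus is nearly circular (`semi_minor / semi_major >
#' circularity_threshold`) the fit center is used directly: near the primary
#' gaze the short axis direction is numerically meaningless.  Otherwise the
#' center is re-assigned along the short (minor) axis: from each of the two
#' minor-axis boundary points, step `limbus_radius` back along the short-axis
#' extension line; of the two candidate centers, the one closer to the
#' modeled sclera center is returned (the limbus center must lie on the
#' eyeball).  In the perfectly symmetric case the candidate displaced toward
#' positive x (positive y on a vertical short axis) is chosen.
#'
#' @param fit an `ellipse_fit` of the segmented limbus.
#' @param limbus_radius limbus radius measured in the primary gaze (px).
#' @param sclera_model the eye's sclera `circle` (same frame as `fit`).
#' @param circularity_threshold minor/major ratio above which the fit is
#'   treated as circular (default 0.95).
#' @return a `circle` with the recovered center and `limbus_radius`.
#' @export
recover_limbus_center <- function(fit, limbus_radius, sclera_model,
                                  circularity_threshold = 0.95) {
  if (!is.finite(limbus_radius) || limbus_radius <= 0)
    stop_strab("strab_invalid_geometry", "limbus_radius must be positive")
  if (fit$semi_minor / fit$semi_major > circularity_threshold)
    return(circle(fit$center, limbus_radius))
  th <- (fit$orientation_deg + 90) * pi / 180  # minor-axis direction
  u <- c(cos(th), sin(th))
  b <- fit$semi_minor
  # boundary point on each side, then step limbus_radius back along the axis
  cand <- list(fit$center + (b - limbus_radius) * u,
               fit$center - (b - limbus_radius) * u)
  d <- vapply(cand, function(p) sqrt(sum((p - sclera_model$center)^2)), numeric(1))
  inside <- d <= sclera_model$radius + 1e-9
  if (!any(inside))
    stop_strab("strab_geometry_inconsistency",
               "both candidate limbus centers fall outside the sclera circle")
  pick <- if (abs(d[1] - d[2]) < 1e-9) {
    disp <- vapply(cand, function(p) p - fit$center, numeric(2))
    if (abs(disp[1, 1] - disp[1, 2]) > 1e-12) which.max(disp[1, ]) else which.max(disp[2, ])
  } else which.min(d)
  if (!inside[pick]) pick <- which(inside)[1]
  circle(as.numeric(cand[[pick]]), limbus_radius)
}
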