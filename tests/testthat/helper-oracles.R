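# Independent oracles used to derive expected values.  These deliberately
# use brute force / exhaustive enumeration and share no code with the
# implementation paths they check.

# O(n^3) minimum enclosing circle: try every pair (diametral circle) and
# every triple (circumcircle), keep the smallest circle containing all
# points.
oracle_mec <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  eps <- 1e-9
  contains_all <- function(ctr, r)
    all((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 <= (r + eps)^2)
  best <- list(center = pts[1, ], radius = Inf)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ctr <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best$radius && contains_all(ctr, r)) best <- list(center = ctr, radius = r)
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    p <- pts[i, ]; q <- pts[j, ]; s <- pts[k, ]
    d <- 2 * (p[1] * (q[2] - s[2]) + q[1] * (s[2] - p[2]) + s[1] * (p[2] - q[2]))
    if (abs(d) < 1e-12) next
    ux <- ((p[1]^2 + p[2]^2) * (q[2] - s[2]) + (q[1]^2 + q[2]^2) * (s[2] - p[2]) +
             (s[1]^2 + s[2]^2) * (p[2] - q[2])) / d
    uy <- ((p[1]^2 + p[2]^2) * (s[1] - q[1]) + (q[1]^2 + q[2]^2) * (p[1] - s[1]) +
             (s[1]^2 + s[2]^2) * (q[1] - p[1])) / d
    r <- sqrt(sum((p - c(ux, uy))^2))
    if (r < best$radius && contains_all(c(ux, uy), r)) best <- list(center = c(ux, uy), radius = r)
  }
  best
}

# Per-pixel inverse-mapping warp oracle (nearest neighbor), explicit loops.
oracle_warp_nearest <- function(raster, scale, rotation_deg, translation, pivot) {
  h <- nrow(raster); w <- ncol(raster)
  th <- rotation_deg * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- pivot + translation - A %*% pivot
  Ai <- solve(A)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    src <- Ai %*% (c(cc - 1, r - 1) - b)
    xs <- round(src[1]); ys <- round(src[2])
    if (xs >= 0 && xs < w && ys >= 0 && ys < h)
      out[r, cc] <- raster[ys + 1, xs + 1]
  }
  if (is.logical(raster)) out > 0.5 else out
}

# Center-of-pixel rasterization of a (rotated) filled ellipse.
raster_ellipse <- function(shape, center, a, b, phi_deg = 0) {
  phi <- phi_deg * pi / 180
  g <- list(x = matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1]),
            y = matrix(rep(0:(shape[1] - 1), times = shape[2]), shape[1]))
  u <- (g$x - center[1]) * cos(phi) + (g$y - center[2]) * sin(phi)
  v <- -(g$x - center[1]) * sin(phi) + (g$y - center[2]) * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

# Exhaustive-scan innermost point (nasal-most) with the spec tie rule.
oracle_innermost <- function(mask, side) {
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  xb <- if (side == "left") max(xs) else min(xs)
  sel <- which(xs == xb)
  sel <- sel[order(ys[sel], xs[sel])][1]
  c(xs[sel], ys[sel])
}

# Ground-truth deviation distances for a synthetic nine-gaze set, aligned
# with a report's measurement rows.
truth_distances <- function(set, measurements) {
  mapply(function(g, e) {
    ee <- set$truth$eyes[[g]][[e]]
    sqrt(sum((ee$limbus_center - set$truth$eyes$primary[[e]]$reflex_point)^2))
  }, measurements$gaze, measurements$eye)
}

expect_point_near <- function(p, q, tol) {
  expect_lt(sqrt(sum((as.numeric(p) - as.numeric(q))^2)), tol)
}

# thin aliases for internal helpers exercised by tests
line_endpoints_for_test <- function(line) strabmetric:::line_endpoints(line)
normalize_angle_for_test <- function(a) strabmetric:::normalize_angle(a)
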