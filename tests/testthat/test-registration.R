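test_that("innermost_points finds nasal-most pixels with the documented tie rule", {
  left <- disk_mask(c(200, 400), c(100, 100), 20)
  right <- disk_mask(c(200, 400), c(300, 100), 20)
  pts <- innermost_points(left, right)
  expect_equal(pts$left, c(120, 100))
  expect_equal(pts$right, c(280, 100))
  # agrees with the exhaustive-scan oracle
  expect_equal(pts$left, oracle_innermost(left, "left"))
  expect_equal(pts$right, oracle_innermost(right, "right"))

  # rectangles: ties broken by minimal y, then minimal x
  rl <- matrix(FALSE, 200, 400); rl[81:121, 51:91] <- TRUE    # x 50..90, y 80..120
  rr <- matrix(FALSE, 200, 400); rr[81:121, 211:251] <- TRUE  # x 210..250
  pts2 <- innermost_points(rl, rr)
  expect_equal(pts2$left, c(90, 80))
  expect_equal(pts2$right, c(210, 80))
  expect_equal(pts2$left, oracle_innermost(rl, "left"))

  expect_error(innermost_points(left, matrix(FALSE, 200, 400)),
               class = "strab_degenerate_mask")
})

test_that("reference_line measures center, length and angle", {
  l1 <- reference_line(c(0, 0), c(100, 0))
  expect_equal(l1$center, c(50, 0)); expect_equal(l1$length, 100)
  expect_equal(l1$angle_deg, 0)
  l2 <- reference_line(c(0, 0), c(0, 100))
  expect_equal(l2$center, c(0, 50)); expect_equal(l2$angle_deg, 90)
  l3 <- reference_line(c(10, 10), c(40, 50))  # 3-4-5 triangle
  expect_equal(l3$length, 50)
  expect_equal(l3$angle_deg, atan2(4, 3) * 180 / pi, tolerance = 1e-10)
  expect_equal(round(l3$angle_deg, 2), 53.13)
  expect_error(reference_line(c(5, 5), c(5, 5)), class = "strab_degenerate_geometry")
})

test_that("solve_similarity maps the moving endpoints onto the fixed endpoints", {
  l <- reference_line(c(10, 20), c(110, 40))
  idt <- solve_similarity(l, l)
  expect_equal(idt$scale, 1); expect_equal(idt$rotation_deg, 0)
  expect_equal(idt$translation, c(0, 0))

  short <- reference_line(c(75, 30) - c(25, 5), c(75, 30) + c(25, 5))
  long <- reference_line(c(75, 30) - c(50, 10), c(75, 30) + c(50, 10))
  expect_equal(solve_similarity(short, long)$scale, 2)

  set.seed(21)
  for (i in 1:25) {
    p <- stats::runif(2, 0, 200); q <- stats::runif(2, 0, 200)
    r <- stats::runif(2, 0, 200); s <- stats::runif(2, 0, 200)
    moving <- reference_line(p, q); fixed <- reference_line(r, s)
    tf <- solve_similarity(moving, fixed)
    expect_point_near(transform_points(tf, p), r, 1e-6)
    expect_point_near(transform_points(tf, q), s, 1e-6)
  }
})

test_that("similarity transforms compose, invert, and round-trip points", {
  set.seed(31)
  for (i in 1:20) {
    t1 <- similarity_transform(scale = stats::runif(1, 0.5, 2),
                               rotation_deg = stats::runif(1, -180, 180),
                               translation = stats::runif(2, -50, 50),
                               pivot = stats::runif(2, 0, 100))
    pts <- matrix(stats::runif(10, 0, 300), 5, 2)
    back <- transform_points(transform_invert(t1), transform_points(t1, pts))
    expect_lt(max(abs(back - pts)), 1e-9)
  }

  # group property on reference lines: (A->B) then (B->C) lands A's
  # endpoints on C's
  for (i in 1:20) {
    ln <- replicate(3, reference_line(stats::runif(2, 0, 200), stats::runif(2, 200, 400)),
                    simplify = FALSE)
    tAB <- solve_similarity(ln[[1]], ln[[2]])
    tBC <- solve_similarity(ln[[2]], ln[[3]])
    comp <- transform_compose(tAB, tBC)
    eA <- line_endpoints_for_test(ln[[1]]); eC <- line_endpoints_for_test(ln[[3]])
    expect_point_near(transform_points(comp, eA$p1), eC$p1, 1e-6)
    expect_point_near(transform_points(comp, eA$p2), eC$p2, 1e-6)
  }
})

test_that("apply_transform matches the brute-force per-pixel oracle", {
  # identity under nearest returns byte-identical raster
  m <- matrix(stats::runif(40 * 40), 40, 40)
  expect_identical(apply_transform(m, similarity_transform(), "nearest"), m)

  # pure translation shifts a mask centroid
  disk <- disk_mask(c(100, 100), c(40, 60), 12)
  tr <- similarity_transform(translation = c(10, -5))
  expect_point_near(mask_centroid(apply_transform(disk, tr, "nearest")),
                    c(50, 55), 0.5)

  # rotation about image center of an asymmetric L-shape: per-pixel oracle
  L <- matrix(FALSE, 41, 41); L[10:30, 12:15] <- TRUE; L[27:30, 12:28] <- TRUE
  tf <- similarity_transform(rotation_deg = 90, pivot = c(20, 20))
  expect_identical(apply_transform(L, tf, "nearest"),
                   oracle_warp_nearest(L, 1, 90, c(0, 0), c(20, 20)))

  # general similarity vs oracle
  tf2 <- similarity_transform(scale = 1.3, rotation_deg = -37,
                              translation = c(3, -2), pivot = c(18, 22))
  expect_identical(apply_transform(L, tf2, "nearest"),
                   oracle_warp_nearest(L, 1.3, -37, c(3, -2), c(18, 22)))
})

test_that("register_gaze aligns a scene onto the primary reference line", {
  set <- make_nine_gaze_set(seed = 5)
  primary <- set$scenes$primary
  pl <- scene_reference_line(primary$sclera_mask)

  # self-registration is the identity
  self <- register_gaze(primary$image, list(sclera = primary$sclera_mask), pl)
  expect_equal(self$transform$scale, 1, tolerance = 0.01)
  expect_equal(self$transform$rotation_deg, 0, tolerance = 0.5)
  expect_lt(max(abs(self$transform$translation)), 1)

  # known jitter J: recovered transform approximates J^-1 on the landmarks
  sc <- set$scenes$up
  reg <- register_gaze(sc$image, list(sclera = sc$sclera_mask,
                                      limbus = sc$limbus_mask), pl)
  J <- set$truth$jitter$up
  pp <- innermost_points(split_eyes(primary$sclera_mask)$left,
                         split_eyes(primary$sclera_mask)$right)
  for (side in c("left", "right")) {
    jittered <- transform_points(J, pp[[side]])
    expect_point_near(transform_points(reg$transform, jittered), pp[[side]], 1.5)
  }

  # the registered scene's re-measured line matches the primary line
  rl <- scene_reference_line(reg$masks$sclera)
  expect_point_near(rl$center, pl$center, 1)
  expect_lt(abs(rl$length - pl$length), 1)
  expect_lt(abs(normalize_angle_for_test(rl$angle_deg - pl$angle_deg)), 0.5)

  # one-component sclera mask fails
  one_eye <- split_eyes(primary$sclera_mask)$left
  expect_error(register_gaze(primary$image, list(sclera = one_eye), pl),
               class = "strab_degenerate_mask")
})

test_that("registering an already-registered scene gives a near-identity transform", {
  set <- make_nine_gaze_set(seed = 9)
  pl <- scene_reference_line(set$scenes$primary$sclera_mask)
  sc <- set$scenes$down_right
  reg1 <- register_gaze(NULL, list(sclera = sc$sclera_mask), pl)
  reg2 <- register_gaze(NULL, list(sclera = reg1$masks$sclera), pl)
  expect_equal(reg2$transform$scale, 1, tolerance = 0.01)
  expect_lt(abs(reg2$transform$rotation_deg), 0.5)
  expect_lt(max(abs(reg2$transform$translation)), 1)
})
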