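test_that("euclidean distance matches hand values and metric properties", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(2, 7), c(2, 7)), 0)
  expect_equal(euclidean_distance(c(1, 1), c(-2, 5)), 5)   # sqrt(9 + 16)
  expect_error(euclidean_distance(c(NA, 0), c(1, 1)), "finite")
  set.seed(42)
  for (i in 1:200) {
    p <- runif(2, -50, 50); q <- runif(2, -50, 50); r <- runif(2, -50, 50)
    expect_identical(euclidean_distance(p, q), euclidean_distance(q, p))
    expect_gte(euclidean_distance(p, q), 0)
    expect_lte(euclidean_distance(p, r),
               euclidean_distance(p, q) + euclidean_distance(q, r) + 1e-12)
  }
})

test_that("segment angle reproduces the slope form on its domain", {
  expect_equal(segment_angle(c(0, 0), c(1, 1), c(2, 2)), 0)   # collinear
  expect_equal(segment_angle(c(0, 0), c(2, 1), c(4, 0)), 0.927295218,
               tolerance = 1e-9)                              # atan(1/0.75)
  expect_equal(segment_angle(c(0, 0), c(0, 1), c(1, 1)), pi / 2)  # vertical seg
  expect_error(segment_angle(c(1, 1), c(1, 1), c(2, 2)), "coincident")
  set.seed(7)
  for (i in 1:300) {
    pts <- matrix(runif(6, -20, 20), 3, 2)
    p1 <- pts[1, ]; p2 <- pts[2, ]; p3 <- pts[3, ]
    a <- segment_angle(p1, p2, p3)
    expect_equal(a, oracle_slope_angle(p1, p2, p3), tolerance = 1e-9)
    expect_equal(abs(a), oracle_acute_angle(p1, p2, p3), tolerance = 1e-9)
    shift <- runif(2, -100, 100)
    expect_equal(segment_angle(p1 + shift, p2 + shift, p3 + shift), a,
                 tolerance = 1e-9)                            # translation inv.
  }
})

test_that("depth features are the distinct pair-list depths in first-occurrence order", {
  fr <- random_frame(3)
  fr[c(4, 7, 19), 3] <- c(0.1, 0.2, 0.3)   # landmarks 3, 6, 18 (0-based)
  expect_equal(depth_features(fr, list(c(3L, 6L), c(6L, 18L))), c(0.1, 0.2, 0.3))
  expect_equal(depth_features(fr, list(c(1L, 2L))), fr[c(2, 3), 3])
  expect_equal(depth_features(fr, list()), numeric(0))
})

test_that("polygon area matches the shoelace oracle and its invariances", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)                    # reversed order
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 points")
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:9, 1)
    pts <- matrix(runif(2 * n, -10, 10), n, 2)
    a <- polygon_area(pts)
    expect_equal(a, oracle_shoelace(pts), tolerance = 1e-12)
    rot <- sample(n)[1]                                       # cyclic rotation
    idx <- c(rot:n, seq_len(rot - 1))
    expect_equal(polygon_area(pts[idx, ]), a, tolerance = 1e-12)
    expect_equal(polygon_area(pts[n:1, ]), a, tolerance = 1e-12)
    cc <- runif(1, 0.5, 3)
    expect_equal(polygon_area(cc * pts), cc^2 * a, tolerance = 1e-9)
  }
})

test_that("principal axes ratio equals the eigen/svd oracle and is rigid-invariant", {
  th <- 2 * pi * (0:7) / 8
  circle <- cbind(cos(th), sin(th))
  expect_equal(principal_axes_ratio(circle), 1, tolerance = 1e-9)
  ellipse <- cbind(2 * cos(th), sin(th))
  expect_equal(principal_axes_ratio(ellipse), 2, tolerance = 1e-9)
  rot37 <- matrix(c(cos(37 * pi / 180), sin(37 * pi / 180),
                    -sin(37 * pi / 180), cos(37 * pi / 180)), 2, 2)
  expect_equal(principal_axes_ratio(circle %*% rot37), 1, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:50) {
    pts <- matrix(rnorm(20, sd = 3), 10, 2) %*% matrix(runif(4, -1, 1), 2, 2)
    if (inherits(try(principal_axes_ratio(pts), silent = TRUE), "try-error")) next
    r <- principal_axes_ratio(pts)
    expect_equal(r, oracle_axes_ratio_svd(pts), tolerance = 1e-9)
    ang <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    moved <- sweep(pts %*% R, 2, runif(2, -30, 30), "+")
    expect_equal(principal_axes_ratio(moved), r, tolerance = 1e-8)
  }
  line <- cbind(1:5, 2 * (1:5))
  expect_error(principal_axes_ratio(line), "collinear")
  expect_identical(principal_axes_ratio(line, collinear = "inf"), Inf)
})

test_that("statistical descriptors follow the fixed conventions", {
  expect_equal(unname(statistical_descriptors(c(1, 2, 3, 4, 5))),
               c(3, sqrt(2), 5, 1, 3, 2, 4))  # population sd of 1..5
  expect_equal(unname(statistical_descriptors(c(7, 7, 7))), c(7, 0, 7, 7, 7, 7, 7))
  expect_equal(unname(statistical_descriptors(4)), c(4, 0, 4, 4, 4, 4, 4))
  expect_error(statistical_descriptors(numeric(0)), "empty")
  set.seed(9)
  for (i in 1:100) {
    x <- rnorm(sample(1:30, 1))
    expect_equal(unname(statistical_descriptors(x)), oracle_descriptors(x),
                 tolerance = 1e-12)
  }
})

test_that("frame features compose distances, angles and depths in config order", {
  cfg <- tiny_config()
  fr <- random_frame(4)
  ff <- frame_features(fr, cfg)
  expect_length(ff$distances, 3)
  expect_length(ff$angles, 2)
  expect_length(ff$depths, 4)            # distinct endpoints of 3 pairs
  expect_equal(ff$distances[1], euclidean_distance(fr[1, 1:2], fr[2, 1:2]))
  expect_equal(ff$angles[2], segment_angle(fr[2, 1:2], fr[3, 1:2], fr[4, 1:2]))
  expect_equal(ff$depths, fr[c(1, 2, 3, 4), 3])
  zero <- matrix(0, 100, 3)
  expect_error(frame_features(zero, cfg), "coincident")   # degenerate angles
})

test_that("feature tracks agree with frame-by-frame recomputation", {
  cfg <- tiny_config()
  s <- simulate_sequence(sim_spec("negative", n_frames = 20, seed = 6))
  track <- extract_features(s, cfg)
  for (i in c(1, 10, 20)) {
    ff <- frame_features(s$points[i, , ], cfg)
    expect_equal(unname(track$distances[i, ]), unname(ff$distances))
    expect_equal(unname(track$angles[i, ]), unname(ff$angles))
    expect_equal(unname(track$depths[i, ]), unname(ff$depths))
  }
  shaped <- extract_features(s, cfg, shape = TRUE)
  g <- doubt_shape_groups()
  i <- 7
  expect_equal(unname(shaped$areas[i, "area_mouth"]),
               polygon_area(s$points[i, g$mouth + 1, 1:2]))
  expect_equal(unname(shaped$eccentricities[i, "ecc_left_eye"]),
               principal_axes_ratio(s$points[i, g$left_eye + 1, 1:2]))
})

test_that("z-score normalization fits on train only and handles constants", {
  fit <- normalize_features(cbind(c(2, 4, 6)))
  expect_equal(mean(fit$matrix), 0)
  expect_equal(sd(fit$matrix), 1)
  applied <- normalize_features(cbind(3), stats = list(center = 2, scale = 1))
  expect_equal(applied$matrix[1, 1], 1)
  const <- normalize_features(cbind(rep(5, 4)))
  expect_equal(as.vector(const$matrix), rep(0, 4))   # centered, scale 1
  set.seed(3)
  x <- matrix(rnorm(200), 20, 10)
  f <- normalize_features(x)
  expect_lt(max(abs(colMeans(f$matrix))), 1e-9)
  expect_lt(max(abs(apply(f$matrix, 2, sd) - 1)), 1e-9)
  expect_error(normalize_features(x, stats = list(center = 1:3, scale = 1:3)),
               "features")
})
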