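test_that("polyline length matches hand values and a brute-force loop", {
  expect_equal(polyline_length(polyline3(rbind(c(0, 0, 0), c(3, 4, 0)))), 5)
  expect_equal(polyline_length(polyline3(rbind(c(1, 1, 1), c(1, 1, 11)))), 10)

  set.seed(11)
  v <- matrix(stats::runif(300, -100, 100), 100, 3)
  loop <- 0
  for (i in 1:99) loop <- loop + sqrt(sum((v[i + 1, ] - v[i, ])^2))
  expect_equal(polyline_length(polyline3(v)), loop, tolerance = 1e-12)
})

test_that("polyline length is invariant under collinear midpoint insertion", {
  set.seed(12)
  for (rep in 1:20) {
    v <- matrix(stats::runif(15, -50, 50), 5, 3)
    len0 <- polyline_length(polyline3(v))
    mids <- (v[-1, , drop = FALSE] + v[-5, , drop = FALSE]) / 2
    v2 <- matrix(NA_real_, 9, 3)
    v2[seq(1, 9, 2), ] <- v
    v2[seq(2, 8, 2), ] <- mids
    expect_equal(polyline_length(polyline3(v2)), len0, tolerance = 1e-9)
  }
})

test_that("point-to-polyline distance: exact cases and dense-sampling oracle", {
  p <- polyline3(rbind(c(-10, 0, 0), c(10, 0, 0)))
  expect_equal(dist_point_polyline(c(0, 5, 0), p), 5)
  expect_equal(dist_point_polyline(c(-10, 0, 0), p), 0)  # on a vertex

  set.seed(13)
  for (rep in 1:40) {
    v <- matrix(stats::runif(12, -50, 50), 4, 3)
    pl <- polyline3(v)
    q <- stats::runif(3, -60, 60)
    mine <- dist_point_polyline(q, pl)
    # dense sampling along every segment over-estimates the true minimum
    oracle <- Inf
    for (i in 1:3) {
      w <- seq(0, 1, length.out = 4000)
      pts <- matrix(v[i, ], 4000, 3, byrow = TRUE) + outer(w, v[i + 1, ] - v[i, ])
      oracle <- min(oracle, sqrt(rowSums(sweep(pts, 2, q)^2)))
    }
    expect_gte(oracle - mine, -1e-12)
    expect_lt(oracle - mine, 1e-3)
  }
})

test_that("segment-segment distance: degenerate, parallel, and grid oracle", {
  expect_equal(dist_segments(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0), c(1, 1, 1)), 0)
  expect_equal(dist_segments(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 2, 0)), 2)

  set.seed(14)
  w <- seq(0, 1, length.out = 250)
  for (rep in 1:60) {
    a1 <- stats::runif(3, -20, 20); b1 <- stats::runif(3, -20, 20)
    a2 <- stats::runif(3, -20, 20); b2 <- stats::runif(3, -20, 20)
    mine <- dist_segments(a1, b1, a2, b2)
    p1 <- matrix(a1, 250, 3, byrow = TRUE) + outer(w, b1 - a1)
    p2 <- matrix(a2, 250, 3, byrow = TRUE) + outer(w, b2 - a2)
    cross <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
    oracle <- sqrt(max(0, min(cross)))
    expect_gte(oracle - mine, -1e-9)
    expect_lt(oracle - mine, 5e-2 * max(1, mine))  # grid resolution bound
    # symmetry
    expect_equal(dist_segments(a2, b2, a1, b1), mine, tolerance = 1e-12)
  }
})

test_that("containment agrees with direct inequalities on random points", {
  set.seed(15)
  s <- sphere(c(1, 2, 3), 7)
  q <- matrix(stats::runif(3000, -10, 15), 1000, 3)
  expect_identical(shape_contains(s, q),
                   sqrt(rowSums(sweep(q, 2, c(1, 2, 3))^2)) <= 7)
  expect_true(shape_contains(s, s$center))
  expect_false(shape_contains(s, s$center + c(7 + 1e-9, 0, 0)))

  cb <- cuboid(c(-1, -2, -3), c(4, 5, 6))
  inside <- q[, 1] >= -1 & q[, 1] <= 4 & q[, 2] >= -2 & q[, 2] <= 5 &
    q[, 3] >= -3 & q[, 3] <= 6
  expect_identical(shape_contains(cb, q), inside)

  cy <- cylinder(c(0, 0, 0), c(0, 10, 0), 3, hollow = TRUE)
  radial <- sqrt(q[, 1]^2 + q[, 3]^2)
  expect_identical(shape_contains(cy, q),
                   radial <= 3 & q[, 2] >= 0 & q[, 2] <= 10)
})

test_that("distances are non-negative and triangle-consistent", {
  set.seed(16)
  for (rep in 1:200) {
    a <- stats::runif(3, -50, 50); b <- stats::runif(3, -50, 50)
    c_ <- stats::runif(3, -50, 50)
    dab <- sqrt(sum((a - b)^2)); dbc <- sqrt(sum((b - c_)^2))
    dac <- sqrt(sum((a - c_)^2))
    expect_lte(dac, dab + dbc + 1e-9)
  }
  p <- polyline3(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_gte(min(dist_point_polyline(matrix(stats::rnorm(300), 100, 3), p)), 0)
})

test_that("shape constructors reject invalid geometry", {
  expect_error(sphere(c(0, 0, 0), -1), "radius")
  expect_error(cylinder(c(0, 0, 0), c(0, 0, 0), 1), "distinct")
  expect_error(cuboid(c(1, 0, 0), c(0, 1, 1)), "min_corner")
  expect_error(polyline3(rbind(c(0, 0, 0))), "at least 2")
  expect_error(polyline3(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
})
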