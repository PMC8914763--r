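test_that("convex hull drops interior points and canonicalizes order", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0.5, 0.5))
  h <- convex_hull(sq)
  expect_equal(nrow(h$vertices), 4L)
  expect_equal(sort_rows(h$vertices), sort_rows(sq[1:4, ]),
               ignore_attr = TRUE)
  # starts at the lexicographically smallest (row, col) vertex
  expect_equal(unname(h$vertices[1, ]), c(0, 0))

  tri <- rbind(c(0, 0), c(4, 1), c(1, 3))
  expect_equal(nrow(convex_hull(tri)$vertices), 3L)

  expect_error(convex_hull(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(convex_hull(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
               "collinear")
})

test_that("convex hull agrees with the convex-combination oracle on random sets", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    pts <- cbind(round(runif(n, 0, 10), 2), round(runif(n, 0, 10), 2))
    pts <- unique(pts)
    if (nrow(pts) < 4) next
    want <- brute_hull_vertices(pts)
    if (nrow(want) < 3) next  # oracle-degenerate draw
    h <- convex_hull(pts)
    expect_equal(sort_rows(h$vertices), sort_rows(want),
                 ignore_attr = TRUE)
    # every input point lies inside or on the hull
    v <- h$vertices
    nn <- nrow(v)
    for (k in seq_len(nn)) {
      j <- if (k == nn) 1L else k + 1L
      cr <- (v[j, 2] - v[k, 2]) * (pts[, 1] - v[k, 1]) -
            (v[j, 1] - v[k, 1]) * (pts[, 2] - v[k, 2])
      expect_true(all(cr > -1e-9))
    }
  }
})

test_that("hull vertices are ordered with positive area and no collinear triples", {
  set.seed(30)
  pts <- cbind(runif(40, 0, 50), runif(40, 0, 50))
  v <- convex_hull(pts)$vertices
  x <- v[, 2]; y <- v[, 1]
  j <- c(2:nrow(v), 1)
  expect_gt(sum(x * y[j] - x[j] * y) / 2, 0)
  for (k in seq_len(nrow(v))) {
    p <- v[if (k == 1) nrow(v) else k - 1, ]
    q <- v[k, ]; r <- v[if (k == nrow(v)) 1 else k + 1, ]
    cr <- (q[1] - p[1]) * (r[2] - q[2]) - (q[2] - p[2]) * (r[1] - q[1])
    expect_gt(abs(cr), 1e-9)
  }
})

test_that("direct least-squares fit recovers a sampled ellipse exactly", {
  pts <- ellipse_points(center = c(60, 50), a = 40, b = 25, angle_deg = 30,
                        n = 12)
  e <- fit_ellipse(pts)
  expect_equal(unname(e$center), c(60, 50), tolerance = 1e-6)
  expect_equal(e$semi_major, 40, tolerance = 1e-6)
  expect_equal(e$semi_minor, 25, tolerance = 1e-6)
  expect_equal(e$angle_deg, 30, tolerance = 1e-6)
  expect_false(e$ambiguous_axis)
  expect_lt(e$residual, 1e-9)
})

test_that("near-circular fits flag the axis as ambiguous", {
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- cbind(10 + 5 * cos(t), 20 + 5 * sin(t))
  e <- fit_ellipse(circ)
  expect_true(e$ambiguous_axis)
  expect_true(symmetry_axis(e)$ambiguous_axis)
})

test_that("degenerate ellipse inputs are rejected", {
  expect_error(fit_ellipse(ellipse_points(c(0, 0), 4, 2, 0, n = 5)),
               "at least 6")
  line <- cbind(1:10, 2 * (1:10))
  expect_error(fit_ellipse(line), "collinear")
})

test_that("ellipse fit is translation-invariant and rotation-equivariant", {
  pts <- ellipse_points(c(0, 0), 9, 4, 20, n = 16)
  e0 <- fit_ellipse(pts)
  e1 <- fit_ellipse(sweep(pts, 2, c(137.2, -58.9), "+"))
  expect_equal(unname(e1$center), unname(e0$center) + c(137.2, -58.9),
               tolerance = 1e-6)
  expect_equal(e1$semi_major, e0$semi_major, tolerance = 1e-6)
  expect_equal(e1$semi_minor, e0$semi_minor, tolerance = 1e-6)
  expect_equal(e1$angle_deg, e0$angle_deg, tolerance = 1e-6)

  for (rot in c(10, -35)) {
    e2 <- fit_ellipse(ellipse_points(c(0, 0), 9, 4, 20 + rot, n = 16))
    expect_equal(e2$angle_deg, 20 + rot, tolerance = 1e-6)
    expect_equal(e2$semi_major, 9, tolerance = 1e-6)
  }
})

test_that("the symmetry axis is the ellipse major axis", {
  pts <- ellipse_points(c(50, 50), 30, 18, 90, n = 20)
  ax <- symmetry_axis(fit_ellipse(pts))
  # vertical major axis: direction is (+-1, 0) in (row, col)
  expect_equal(abs(ax$direction[1]), 1, tolerance = 1e-9)
  expect_equal(ax$direction[2], 0, tolerance = 1e-9)
  expect_equal(ax$point, c(50, 50), tolerance = 1e-6)
})

test_that("the phantom symmetry axis is recovered to sub-degree accuracy", {
  for (ang in c(-10, 0, 12)) {
    spec <- small_spec(noise_sd_c = 0, axis_angle_deg = ang)
    ph <- make_face_phantom(spec)
    pts <- detect_edges(ph$thermogram)$points
    e <- fit_ellipse(convex_hull(pts)$vertices)
    ax <- symmetry_axis(e)
    got_from_vertical <- 90 - e$angle_deg
    if (got_from_vertical > 90) got_from_vertical <- got_from_vertical - 180
    expect_lt(abs(got_from_vertical - ang), 0.5)
    # axis-to-true-axis distance at the face center
    delta <- spec$face_center - ax$point
    dist <- abs(delta[1] * ax$direction[2] - delta[2] * ax$direction[1])
    expect_lt(dist, 1)
  }
  # tilting the phantom by 10 degrees tilts the recovered axis by 10 +- 0.5
  rec <- vapply(c(0, 10), function(ang) {
    ph <- make_face_phantom(small_spec(noise_sd_c = 0, axis_angle_deg = ang))
    90 - fit_ellipse(
      convex_hull(detect_edges(ph$thermogram)$points)$vertices)$angle_deg
  }, numeric(1))
  expect_equal(rec[2] - rec[1], 10, tolerance = 0.5)
})

test_that("region splitting matches a hand enumeration on a toy grid", {
  v <- matrix(30 + seq_len(36) / 10, 6, 6)
  tg <- thermogram(v)
  hull <- convex_hull(rbind(c(1.5, 1.5), c(1.5, 5.5), c(5.5, 5.5),
                            c(5.5, 1.5)))
  ax <- structure(list(point = c(3, 3.5), direction = c(1, 0),
                       ambiguous_axis = FALSE), class = "axis_line")
  pr <- split_regions(tg, hull, ax)
  # strictly inside: rows 2..5, cols 2..5; side sign = -(col - 3.5)
  inside <- expand.grid(row = 2:5, col = 2:5)
  want_a <- inside[inside$col < 3.5, ]
  want_b <- inside[inside$col > 3.5, ]
  expect_equal(sort_rows(pr$side_a_pixels), sort_rows(as.matrix(want_a)),
               ignore_attr = TRUE)
  expect_equal(sort_rows(pr$side_b_pixels), sort_rows(as.matrix(want_b)),
               ignore_attr = TRUE)
  expect_equal(pr$n_on_axis, 0L)
  expect_setequal(pr$side_a_temps, v[as.matrix(want_a)])

  # integer-column axis: one pixel column sits exactly on the axis
  ax3 <- structure(list(point = c(3, 3), direction = c(1, 0),
                       ambiguous_axis = FALSE), class = "axis_line")
  pr3 <- split_regions(tg, hull, ax3)
  expect_equal(pr3$n_on_axis, 4L)
  expect_equal(nrow(pr3$side_a_pixels) + nrow(pr3$side_b_pixels) +
                 pr3$n_on_axis, 16L)
})

test_that("an axis missing the hull is an error, as is an empty side", {
  tg <- thermogram(matrix(31, 8, 8))
  hull <- convex_hull(rbind(c(1.5, 1.5), c(1.5, 5.5), c(5.5, 5.5),
                            c(5.5, 1.5)))
  ax_far <- structure(list(point = c(3, 7.5), direction = c(1, 0),
                           ambiguous_axis = FALSE), class = "axis_line")
  expect_error(split_regions(tg, hull, ax_far), "does not intersect")
})

test_that("splitting a symmetric phantom balances the two sides", {
  ph <- make_face_phantom(small_spec(noise_sd_c = 0))
  tg <- ph$thermogram
  hull <- convex_hull(detect_edges(tg)$points)
  ax <- structure(list(point = c(40, 50), direction = c(1, 0),
                       ambiguous_axis = FALSE), class = "axis_line")
  pr <- split_regions(tg, hull, ax)
  expect_equal(mean(pr$side_a_temps), mean(pr$side_b_temps),
               tolerance = 1e-12)
  expect_equal(length(pr$side_a_temps), length(pr$side_b_temps))
})
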