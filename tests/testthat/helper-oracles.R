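# Independent brute-force oracles and small fixtures shared across the
# suite. Everything here is deliberately naive (loops, enumeration) and
# shares no code path with the package implementation it checks.

# A small phantom geometry used where full 240x320 frames would be waste.
small_spec <- function(...) {
  phantom_spec(shape = c(80L, 100L), face_center = c(40, 50),
               face_semiaxes = c(30, 22), ...)
}

# --- convex hull oracle -----------------------------------------------------
# A point is a hull vertex iff it is NOT a convex combination of the other
# points; in the plane (Caratheodory) that means: not equal to, on a
# segment between, or inside a triangle of other points.

on_segment <- function(p, a, b, tol = 1e-9) {
  cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  if (abs(cr) > tol) return(FALSE)
  d <- sum((p - a) * (b - a))
  d >= -tol && d <= sum((b - a)^2) + tol
}

in_triangle <- function(p, a, b, c, tol = 1e-9) {
  s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
  s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
  (s1 >= -tol && s2 >= -tol && s3 >= -tol) ||
    (s1 <= tol && s2 <= tol && s3 <= tol)
}

brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  is_vertex <- rep(TRUE, n)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    others <- pts[-i, , drop = FALSE]
    m <- nrow(others)
    found <- FALSE
    for (j in seq_len(m - 1)) {
      for (k in (j + 1):m) {
        if (on_segment(p, others[j, ], others[k, ])) { found <- TRUE; break }
        if (k < m) for (l in (k + 1):m) {
          if (in_triangle(p, others[j, ], others[k, ], others[l, ])) {
            found <- TRUE; break
          }
        }
        if (found) break
      }
      if (found) break
    }
    is_vertex[i] <- !found
  }
  pts[is_vertex, , drop = FALSE]
}

sort_rows <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]

# --- region pair fixtures and feature oracle --------------------------------

random_region_pair <- function(n_a = NULL, n_b = NULL) {
  if (is.null(n_a)) n_a <- sample(5:60, 1)
  if (is.null(n_b)) n_b <- sample(5:60, 1)
  structure(list(side_a_temps = round(runif(n_a, 30, 36), 3),
                 side_b_temps = round(runif(n_b, 30, 36), 3),
                 side_a_pixels = cbind(row = seq_len(n_a), col = 1L),
                 side_b_pixels = cbind(row = seq_len(n_b), col = 2L),
                 n_on_axis = 0L),
            class = "region_pair")
}

swap_sides <- function(pair) {
  structure(list(side_a_temps = pair$side_b_temps,
                 side_b_temps = pair$side_a_temps,
                 side_a_pixels = pair$side_b_pixels,
                 side_b_pixels = pair$side_a_pixels,
                 n_on_axis = pair$n_on_axis),
            class = "region_pair")
}

shift_pair <- function(pair, offset) {
  pair$side_a_temps <- pair$side_a_temps + offset
  pair$side_b_temps <- pair$side_b_temps + offset
  pair
}

# Loop-based recomputation of all eight features from scratch.
brute_features <- function(face_pair, mouth_pair, delta_t) {
  one <- function(pair) {
    a <- pair$side_a_temps; b <- pair$side_b_temps
    ma <- sum(a) / length(a); mb <- sum(b) / length(b)
    mada <- sum(abs(a - ma)) / length(a)
    madb <- sum(abs(b - mb)) / length(b)
    warm <- if (ma >= mb) a else b
    cool <- if (ma >= mb) b else a
    cnt <- 0L
    for (x in warm) if (x > max(cool) + delta_t) cnt <- cnt + 1L
    c(abs(ma - mb), abs(max(a) - max(b)), cnt, abs(mada - madb))
  }
  out <- c(one(face_pair), one(mouth_pair))
  names(out) <- feature_names
  out
}

# --- classifier oracles -----------------------------------------------------

brute_nn_label <- function(test_vec, X, y) {
  best_d <- Inf; best_i <- NA_integer_
  for (i in seq_len(nrow(X))) {
    d <- sqrt(sum((test_vec - X[i, ])^2))
    if (d < best_d) { best_d <- d; best_i <- i }
  }
  y[best_i]
}

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Points sampled exactly on an ellipse, in (row, col) coordinates.
# angle_deg is the major-axis orientation from the column axis.
ellipse_points <- function(center, a, b, angle_deg, n = 12,
                           t = seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]) {
  th <- angle_deg * pi / 180
  d <- c(sin(th), cos(th))      # (row, col) unit vector of the major axis
  nv <- c(cos(th), -sin(th))    # perpendicular
  cbind(row = center[1] + a * cos(t) * d[1] + b * sin(t) * nv[1],
        col = center[2] + a * cos(t) * d[2] + b * sin(t) * nv[2])
}
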