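#' Convex hull of a set of pixel points
#'
#' The smallest convex polygon containing all input points, built on the
#' monotone-chain hull in base R ([grDevices::chull()]) and
#' post-processed to a canonical form: vertices ordered counterclockwise
#' in the `(col, row)` plane, starting from the lexicographically
#' smallest `(row, col)` vertex, with no three consecutive vertices
#' collinear.
#'
#' @param points numeric matrix or data frame with two columns
#'   `(row, col)`; at least 3 non-collinear points.
#' @return An object of class `"hull"`: a list with `vertices`, an
#'   n x 2 matrix of `(row, col)` coordinates.
#' @export
convex_hull <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (row, col)")
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 3L) stop("need at least 3 distinct points for a hull")
  idx <- grDevices::chull(pts[, 2], pts[, 1])
  v <- pts[idx, , drop = FALSE]
  if (nrow(v) < 3L || abs(polygon_area(v)) < 1e-12)
    stop("degenerate hull: points are collinear")
  if (polygon_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v <- drop_collinear(v)
  start <- order(v[, 1], v[, 2])[1]
  v <- v[c(start:nrow(v), seq_len(start - 1L)), , drop = FALSE]
  dimnames(v) <- list(NULL, c("row", "col"))
  structure(list(vertices = v), class = "hull")
}

# Signed polygon area in the (x = col, y = row) plane; positive for the
# orientation this package calls counterclockwise.
polygon_area <- function(v) {
  x <- v[, 2]; y <- v[, 1]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

drop_collinear <- function(v, tol = 1e-9) {
  repeat {
    n <- nrow(v)
    if (n <= 3L) return(v)
    ip <- c(n, seq_len(n - 1L)); nx <- c(seq_len(n)[-1], 1L)
    cr <- cross2(v[, 1] - v[ip, 1], v[, 2] - v[ip, 2],
                 v[nx, 1] - v[, 1], v[nx, 2] - v[, 2])
    keep <- abs(cr) > tol
    if (all(keep)) return(v)
    v <- v[keep, , drop = FALSE]
  }
}

# Which of the points (r, c) lie inside a convex hull (strictly, by
# default). Vectorized over points.
in_hull <- function(r, c, hull, strict = TRUE, tol = 1e-9) {
  v <- hull$vertices
  n <- nrow(v)
  inside <- rep(TRUE, length(r))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # cross product of the directed edge with (point - vertex) in the
    # (x = col, y = row) plane; positive inside for positive-area order
    cr <- (v[j, 2] - v[i, 2]) * (r - v[i, 1]) -
          (v[j, 1] - v[i, 1]) * (c - v[i, 2])
    inside <- inside & (if (strict) cr > tol else cr > -tol)
    if (!any(inside)) break
  }
  inside
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic that minimizes the algebraic least-squares error over
#' the points, constrained to be an ellipse (the numerically stabilized
#' formulation of the direct Fitzgibbon fit). The method is
#' non-iterative, needs no initialization, and always returns an ellipse
#' when one exists. Input coordinates are centered and scaled internally
#' for conditioning; results are reported in the original frame.
#'
#' @param points numeric matrix with columns `(row, col)`; at least 6
#'   points not all on a line.
#' @return An object of class `"ellipse_params"`: `center` `(row, col)`,
#'   `semi_major`, `semi_minor` (pixels), `angle_deg` (orientation of
#'   the major axis in `(-90, 90]`, degrees from the column axis toward
#'   increasing row), `residual` (mean absolute algebraic residual in
#'   the normalized frame), and `ambiguous_axis` (`TRUE` when the fit is
#'   near-circular, axis ratio < 1.02, so the major-axis direction is
#'   not meaningful).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (row, col)")
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 6L) stop("ellipse fit needs at least 6 distinct points")
  y0r <- pts[, 1]; x0c <- pts[, 2]
  mx <- mean(x0c); my <- mean(y0r)
  sc <- mean(sqrt((x0c - mx)^2 + (y0r - my)^2))
  if (sc < 1e-12) stop("degenerate point scatter")
  x <- (x0c - mx) / sc; y <- (y0r - my) / sc
  if (svd(cbind(x, y))$d[2] < 1e-9)
    stop("points are collinear; cannot fit an ellipse")

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  vec <- Re(eg$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L)
    stop("degenerate scatter: best-fit conic is not an ellipse")
  a1 <- vec[, ok[1]]
  coef <- c(a1, as.numeric(Tm %*% a1))  # A B C D E F in normalized frame
  # the solved coefficient vector has arbitrary overall sign; fix A + C > 0
  # so the quadratic-form eigenvalues are positive and ordered consistently
  if (coef[1] + coef[3] < 0) coef <- -coef

  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  xc <- (2 * C * D - B * E) / den
  yc <- (2 * A * E - B * D) / den
  mu <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)      # values in decreasing order
  if (mu * eq$values[1] >= 0 || mu * eq$values[2] >= 0)
    stop("degenerate scatter: best-fit conic is not an ellipse")
  semi <- sqrt(-mu / eq$values)          # (minor, major): larger lambda first
  vmaj <- eq$vectors[, 2]                # eigenvector of the smaller lambda
  ang <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  resid <- mean(abs(cbind(D1, D2) %*% coef)) / sqrt(sum(coef^2))
  structure(list(center = c(row = yc * sc + my, col = xc * sc + mx),
                 semi_major = semi[2] * sc, semi_minor = semi[1] * sc,
                 angle_deg = ang, residual = resid,
                 ambiguous_axis = semi[2] / semi[1] < 1.02),
            class = "ellipse_params")
}

#' Symmetry axis of a fitted ellipse
#'
#' The symmetry axis of the face (or mouth cavity) is the major axis of
#' the ellipse fitted to the convex-hull vertices of its edge points.
#'
#' @param ellipse an `"ellipse_params"` object from [fit_ellipse()].
#' @return An object of class `"axis_line"`: `point` (`(row, col)` on
#'   the line), `direction` (unit `(row, col)` vector), and
#'   `ambiguous_axis` propagated from the fit.
#' @export
symmetry_axis <- function(ellipse) {
  stopifnot(inherits(ellipse, "ellipse_params"))
  th <- ellipse$angle_deg * pi / 180
  structure(list(point = as.numeric(ellipse$center),
                 direction = c(sin(th), cos(th)),
                 ambiguous_axis = isTRUE(ellipse$ambiguous_axis)),
            class = "axis_line")
}

#' Split the analysis field into the two sides of the symmetry axis
#'
#' Every pixel whose center lies strictly inside the hull polygon is
#' assigned to side A or side B by the sign of the 2-D cross product of
#' `(pixel - axis$point)` with the axis direction; pixels exactly on the
#' axis are discarded, which keeps the two sides disjoint. Side labels
#' are geometric, not anatomical: all downstream features are invariant
#' to swapping them.
#'
#' @param tg a [thermogram()].
#' @param hull a [convex_hull()] of the view's edge points.
#' @param axis an [symmetry_axis()] line; must intersect the hull.
#' @return An object of class `"region_pair"`: `side_a_temps`,
#'   `side_b_temps` (numeric vectors, C), `side_a_pixels`,
#'   `side_b_pixels` (n x 2 `(row, col)` matrices) and `n_on_axis`, the
#'   number of discarded on-axis pixels.
#' @export
split_regions <- function(tg, hull, axis) {
  stopifnot(inherits(tg, "thermogram"), inherits(hull, "hull"),
            inherits(axis, "axis_line"))
  eps <- 1e-9
  v <- hull$vertices
  sv <- cross2(v[, 1] - axis$point[1], v[, 2] - axis$point[2],
               axis$direction[1], axis$direction[2])
  if (all(sv > eps) || all(sv < -eps))
    stop("axis does not intersect the hull polygon")
  nr <- nrow(tg$values); nc <- ncol(tg$values)
  r0 <- max(1L, floor(min(v[, 1]))); r1 <- min(nr, ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2]))); c1 <- min(nc, ceiling(max(v[, 2])))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  ok <- in_hull(rr, cc, hull, strict = TRUE, tol = eps)
  rr <- rr[ok]; cc <- cc[ok]
  if (length(rr) == 0L) stop("degenerate split: no pixels inside hull")
  s <- cross2(rr - axis$point[1], cc - axis$point[2],
              axis$direction[1], axis$direction[2])
  a <- s > eps; b <- s < -eps
  if (!any(a) || !any(b))
    stop("degenerate split: one side of the axis is empty")
  temps <- tg$values[cbind(rr, cc)]
  structure(list(side_a_temps = temps[a], side_b_temps = temps[b],
                 side_a_pixels = cbind(row = rr[a], col = cc[a]),
                 side_b_pixels = cbind(row = rr[b], col = cc[b]),
                 n_on_axis = sum(!a & !b)),
            class = "region_pair")
}
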