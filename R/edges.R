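#' Prewitt gradient of a thermogram
#'
#' Convolves the temperature grid with the 3x3 Prewitt kernels to obtain
#' the horizontal (`gx`, along columns) and vertical (`gy`, along rows)
#' first derivatives and their magnitude. Image borders are handled by
#' edge replication, which avoids the spurious frame gradients that
#' zero-padding would create.
#'
#' With this convention an isolated vertical temperature step of height
#' `h` produces `|gx| = 3 h` on the two columns adjacent to the step.
#'
#' @param tg a [thermogram()] of at least 3x3 pixels.
#' @return A list of class `"gradient_field"` with matrices `gx`, `gy`
#'   and `magnitude` (`sqrt(gx^2 + gy^2)`), all in C per pixel and the
#'   same shape as the input.
#' @export
prewitt_gradient <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  v <- tg$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3L || nc < 3L) stop("image must be at least 3x3 for gradients")
  p <- v[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]  # replicate borders
  sh <- function(dr, dc) p[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  gx <- (sh(-1L, 1L) + sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + sh(-1L, 0L) + sh(-1L, 1L))
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2)),
            class = "gradient_field")
}

#' Detect edge pixels by gradient-magnitude thresholding
#'
#' A pixel is an edge pixel when its Prewitt gradient magnitude is at
#' least `edge_threshold_frac` times the maximum magnitude within the
#' region of interest. The relative threshold makes the edge map
#' invariant to constant temperature offsets and to any uniform scaling
#' of the gradient kernels.
#'
#' @param tg a [thermogram()].
#' @param config a [pipeline_config()]; supplies `edge_threshold_frac`.
#' @param roi_mask optional logical matrix of the same shape restricting
#'   both the threshold reference and the reported edge pixels (used for
#'   the warm mouth-cavity ROI in the open-mouth view).
#' @return A list of class `"edge_map"` with `mask` (logical matrix) and
#'   `points` (integer matrix of `(row, col)` positions of the edge
#'   pixels).
#' @export
detect_edges <- function(tg, config = pipeline_config(), roi_mask = NULL) {
  g <- prewitt_gradient(tg)
  mag <- g$magnitude
  if (!is.null(roi_mask)) {
    if (!is.logical(roi_mask) || !identical(dim(roi_mask), dim(mag)))
      stop("roi_mask must be a logical matrix with the thermogram's shape")
    if (!any(roi_mask)) stop("roi_mask selects no pixels")
  }
  ref <- if (is.null(roi_mask)) max(mag) else max(mag[roi_mask])
  if (ref <= 0)
    stop("no edges: gradient magnitude is zero everywhere in the ROI")
  mask <- mag >= config$edge_threshold_frac * ref
  if (!is.null(roi_mask)) mask <- mask & roi_mask
  pts <- which(mask, arr.ind = TRUE)
  colnames(pts) <- c("row", "col")
  structure(list(mask = mask, points = pts), class = "edge_map")
}

#' Warm-region mask for the open-mouth view
#'
#' The open mouth cavity is the warmest area of the image; pixels at or
#' above `mouth_temp_floor_c` form the ROI within which mouth-cavity
#' edges are detected.
#'
#' @param tg a [thermogram()].
#' @param config a [pipeline_config()].
#' @return Logical matrix of the thermogram's shape.
#' @export
mouth_roi_mask <- function(tg, config = pipeline_config()) {
  tg$values >= config$mouth_temp_floor_c
}
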