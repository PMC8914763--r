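#' Names of the eight asymmetry features, in canonical order
#'
#' `dTf`/`dTm`: absolute difference of side mean temperatures (face /
#' mouth cavity). `dTfmax`/`dTmmax`: absolute difference of side maximum
#' temperatures. `nf`/`nm`: number of pixels on the warmer side
#' exceeding the cooler side's maximum by more than the asymmetry
#' threshold. `dDEVf`/`dDEVm`: absolute difference of the side mean
#' absolute deviations.
#'
#' @export
feature_names <- c("dTf", "dTfmax", "nf", "dDEVf",
                   "dTm", "dTmmax", "nm", "dDEVm")

#' Summary statistics of one side's temperature collection
#'
#' @param temps nonempty numeric vector of temperatures, C.
#' @return Named numeric vector `(mean, max, mad)`, where `mad` is the
#'   mean absolute deviation about the mean.
#' @export
region_summary <- function(temps) {
  if (length(temps) == 0L) stop("empty temperature collection")
  m <- mean(temps)
  c(mean = m, max = max(temps), mad = mean(abs(temps - m)))
}

#' Exceedance pixel count between the two sides
#'
#' Identifies the warmer side (larger mean temperature) and counts its
#' pixels whose temperature strictly exceeds the cooler side's maximum
#' plus `delta_t`. This is the histogram-based count underlying the
#' `nf`/`nm` features; it is zero for symmetric regions.
#'
#' @param pair a [split_regions()] result.
#' @param delta_t exceedance margin in C, > 0 (the 0.4 C asymmetry
#'   threshold by default in the pipeline).
#' @return Integer count.
#' @export
count_exceeding <- function(pair, delta_t) {
  stopifnot(inherits(pair, "region_pair"))
  if (delta_t <= 0) stop("delta_t must be > 0")
  if (mean(pair$side_a_temps) >= mean(pair$side_b_temps)) {
    warm <- pair$side_a_temps; cool <- pair$side_b_temps
  } else {
    warm <- pair$side_b_temps; cool <- pair$side_a_temps
  }
  sum(warm > max(cool) + delta_t)
}

#' Extract the eight-feature asymmetry vector for one patient
#'
#' All differences are taken as absolute values, so the vector is
#' invariant to swapping the geometric side labels and carries no
#' anatomical left/right convention.
#'
#' @param face_pair,mouth_pair [split_regions()] results for the face
#'   and open-mouth views.
#' @param config a [pipeline_config()]; supplies the exceedance
#'   threshold.
#' @param patient_id opaque label attached to the vector.
#' @return An object of class `"feature_vector"`: a named numeric
#'   vector in [feature_names] order with attribute `patient_id`.
#' @export
extract_features <- function(face_pair, mouth_pair,
                             config = pipeline_config(),
                             patient_id = "unlabeled") {
  one_view <- function(pair) {
    a <- region_summary(pair$side_a_temps)
    b <- region_summary(pair$side_b_temps)
    c(abs(a["mean"] - b["mean"]), abs(a["max"] - b["max"]),
      count_exceeding(pair, config$delta_t_threshold_c),
      abs(a["mad"] - b["mad"]))
  }
  fv <- c(one_view(face_pair), one_view(mouth_pair))
  names(fv) <- feature_names
  structure(fv, patient_id = as.character(patient_id),
            class = "feature_vector")
}

# Edge detection + convex hull for one view; the mouth view is first
# restricted to the warm-cavity ROI.
view_edge_points <- function(tg, config) {
  roi <- if (tg$view == "mouth") {
    m <- mouth_roi_mask(tg, config)
    if (!any(m))
      stop(sprintf("no pixels above mouth_temp_floor_c = %g C",
                   config$mouth_temp_floor_c))
    m
  } else NULL
  detect_edges(tg, config, roi_mask = roi)$points
}

# One axis estimate from a (possibly perturbed) point cloud.
estimate_pair <- function(tg, pts) {
  hull <- convex_hull(pts)
  axis <- symmetry_axis(fit_ellipse(hull$vertices))
  split_regions(tg, hull, axis)
}

#' Feature vector averaged over repeated contour estimates
#'
#' Runs the full edge detection, convex hull, ellipse fit, axis and
#' region-split chain `n_estimates` times per view. The first estimate
#' uses the hull vertices as detected; each later estimate perturbs
#' every hull vertex by an independent uniform offset in
#' `[-jitter_px, +jitter_px]` per coordinate (emulating the re-drawing
#' of a few contour points between manual re-estimates) and re-hulls the
#' perturbed cloud before fitting. The reported vector is the
#' componentwise mean over the estimates, so the count features may be
#' fractional. Estimates that fail (degenerate split) are discarded; an
#' error is raised only if all fail.
#'
#' @param face_tg,mouth_tg [thermogram()]s of the two views.
#' @param config a [pipeline_config()].
#' @param seed integer seed driving the jitter; results are
#'   deterministic given the seed.
#' @param patient_id label attached to the vector (defaults to the face
#'   thermogram's id).
#' @return A `"feature_vector"`.
#' @export
averaged_features <- function(face_tg, mouth_tg,
                              config = pipeline_config(),
                              seed = config$rng_seed,
                              patient_id = face_tg$id) {
  pts_f <- view_edge_points(face_tg, config)
  pts_m <- view_edge_points(mouth_tg, config)
  hv_f <- convex_hull(pts_f)$vertices
  hv_m <- convex_hull(pts_m)$vertices
  ests <- with_seed(seed, lapply(seq_len(config$n_estimates), function(i) {
    jf <- if (i == 1L) hv_f else
      hv_f + matrix(stats::runif(length(hv_f), -config$jitter_px,
                                 config$jitter_px), nrow(hv_f), 2L)
    jm <- if (i == 1L) hv_m else
      hv_m + matrix(stats::runif(length(hv_m), -config$jitter_px,
                                 config$jitter_px), nrow(hv_m), 2L)
    tryCatch({
      fp <- estimate_pair(face_tg, jf)
      mp <- estimate_pair(mouth_tg, jm)
      extract_features(fp, mp, config, patient_id)
    }, error = function(e) NULL)
  }))
  ests <- ests[!vapply(ests, is.null, logical(1))]
  if (length(ests) == 0L)
    stop(sprintf("all %d contour estimates failed for patient '%s'",
                 config$n_estimates, patient_id))
  fv <- colMeans(do.call(rbind, ests))
  structure(fv, patient_id = as.character(patient_id),
            class = "feature_vector")
}

#' Baseline asymmetry screen at the 0.4 C threshold
#'
#' The transparent non-ML decision rule: a patient is flagged as
#' thermally asymmetric when the larger of the face and mouth mean-
#' temperature asymmetries exceeds the threshold. Asymmetry of exactly
#' the threshold value still counts as normal.
#'
#' @param fv a `"feature_vector"`.
#' @param config a [pipeline_config()]; supplies `delta_t_threshold_c`.
#' @return `TRUE` when `max(dTf, dTm) > delta_t_threshold_c`.
#' @export
is_asymmetric <- function(fv, config = pipeline_config()) {
  max(fv[["dTf"]], fv[["dTm"]]) > config$delta_t_threshold_c
}

#' Write / read a feature matrix
#'
#' Tab-separated interchange format between feature extraction and
#' classification: one row per patient with `patient_id`, the eight
#' features in [feature_names] order, and an optional integer `label`
#' column (0 = non-tumor, 1 = tumor).
#'
#' @param vectors list of `"feature_vector"` objects.
#' @param labels optional integer vector of 0/1 class labels.
#' @param path file path.
#' @return `write_feature_matrix()`: `path` invisibly;
#'   `read_feature_matrix()`: a list with `features` (numeric matrix,
#'   patient ids as rownames) and `labels` (integer vector or `NULL`).
#' @export
write_feature_matrix <- function(vectors, path, labels = NULL) {
  mat <- do.call(rbind, lapply(vectors, as.numeric))
  colnames(mat) <- feature_names
  df <- data.frame(
    patient_id = vapply(vectors, function(v) attr(v, "patient_id"),
                        character(1)),
    apply(mat, 2L, function(x) sprintf("%.10g", x)))
  colnames(df) <- c("patient_id", feature_names)
  if (!is.null(labels)) df$label <- as.integer(labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(feature_names %in% colnames(df)))
    stop("feature matrix file is missing feature columns")
  mat <- as.matrix(df[, feature_names])
  rownames(mat) <- df$patient_id
  list(features = mat,
       labels = if ("label" %in% colnames(df)) as.integer(df$label) else NULL)
}
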