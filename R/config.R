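#' Pipeline configuration
#'
#' Collects every tunable parameter of the asymmetry pipeline with its
#' default. All temperatures are in degrees Celsius, all lengths in
#' pixels.
#'
#' @param delta_t_threshold_c asymmetry threshold separating normal
#'   bilateral variation from abnormality; also the exceedance margin of
#'   the pixel-count features. Default 0.4.
#' @param edge_threshold_frac fraction of the maximum gradient magnitude
#'   (within the ROI, if any) above which a pixel counts as an edge
#'   pixel, in (0, 1). Default 0.2.
#' @param body_temp_floor_c lower bound of plausible facial skin
#'   temperature, used only for sanity reporting. Default 27.
#' @param mouth_temp_floor_c temperature above which a pixel belongs to
#'   the warm mouth-cavity ROI in the open-mouth view. Default 34.5.
#' @param n_estimates number of contour re-estimates averaged per feature
#'   vector. Default 5.
#' @param jitter_px half-width of the uniform perturbation applied to
#'   hull vertices in re-estimates 2..n_estimates. Default 1.
#' @param k_neighbors number of neighbors for the classifier; must be
#'   odd. Default 1.
#' @param standardize_features z-score features with training-set
#'   statistics before computing distances. Default `TRUE`.
#' @param n_train_per_class training-set size per class in each split.
#'   Default 12.
#' @param n_repeats number of random train/test repetitions pooled into
#'   one report. Default 12.
#' @param rng_seed default seed used when a function is not given one
#'   explicitly.
#' @param min_temp_c,max_temp_c physical plausibility window for input
#'   temperatures. Default -20 to 250.
#' @return An object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(delta_t_threshold_c = 0.4,
                            edge_threshold_frac = 0.2,
                            body_temp_floor_c = 27.0,
                            mouth_temp_floor_c = 34.5,
                            n_estimates = 5L,
                            jitter_px = 1,
                            k_neighbors = 1L,
                            standardize_features = TRUE,
                            n_train_per_class = 12L,
                            n_repeats = 12L,
                            rng_seed = 1L,
                            min_temp_c = -20,
                            max_temp_c = 250) {
  cfg <- list(delta_t_threshold_c = as.numeric(delta_t_threshold_c),
              edge_threshold_frac = as.numeric(edge_threshold_frac),
              body_temp_floor_c = as.numeric(body_temp_floor_c),
              mouth_temp_floor_c = as.numeric(mouth_temp_floor_c),
              n_estimates = as.integer(n_estimates),
              jitter_px = as.numeric(jitter_px),
              k_neighbors = as.integer(k_neighbors),
              standardize_features = isTRUE(standardize_features),
              n_train_per_class = as.integer(n_train_per_class),
              n_repeats = as.integer(n_repeats),
              rng_seed = as.integer(rng_seed),
              min_temp_c = as.numeric(min_temp_c),
              max_temp_c = as.numeric(max_temp_c))
  if (cfg$delta_t_threshold_c <= 0) stop("delta_t_threshold_c must be > 0")
  if (cfg$edge_threshold_frac <= 0 || cfg$edge_threshold_frac >= 1)
    stop("edge_threshold_frac must be in (0, 1)")
  if (cfg$k_neighbors < 1L || cfg$k_neighbors %% 2L == 0L)
    stop("k_neighbors must be a positive odd integer")
  if (cfg$n_estimates < 1L) stop("n_estimates must be >= 1")
  if (cfg$jitter_px < 0) stop("jitter_px must be >= 0")
  if (cfg$n_train_per_class < 1L || cfg$n_repeats < 1L)
    stop("n_train_per_class and n_repeats must be >= 1")
  if (cfg$min_temp_c >= cfg$max_temp_c)
    stop("min_temp_c must be below max_temp_c")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file holds a flat key-value mapping of [pipeline_config()] fields;
#' every key is optional and missing keys take the documented defaults.
#' The format is chosen by extension (`.json` for JSON, anything else is
#' parsed as YAML).
#'
#' @param path path to the configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
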