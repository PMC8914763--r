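#' Feature extraction over a whole cohort
#'
#' Runs [averaged_features()] for every cohort member with per-member
#' seeds derived deterministically from `seed`. Members whose feature
#' extraction fails are excluded and reported, mirroring how
#' unprocessable images are dropped from a study rather than aborting
#' it.
#'
#' @param cohort list of members, each with `id`, `face`, `mouth`
#'   [thermogram()]s and (optionally) `truth$class_label` — the shape
#'   produced by [make_cohort()].
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @return A list with `vectors` (feature vectors), `labels` (integer
#'   vector or `NULL` when no member carries a label) and `excluded`
#'   (character vector of member ids that failed).
#' @export
cohort_features <- function(cohort, config = pipeline_config(),
                            seed = config$rng_seed) {
  seeds <- derive_seeds(seed, length(cohort))
  vectors <- list(); labels <- integer(0); excluded <- character(0)
  for (i in seq_along(cohort)) {
    m <- cohort[[i]]
    fv <- tryCatch(
      averaged_features(m$face, m$mouth, config, seed = seeds[i],
                        patient_id = m$id),
      error = function(e) {
        warning(sprintf("excluding '%s': %s", m$id, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(fv)) { excluded <- c(excluded, m$id); next }
    vectors[[length(vectors) + 1L]] <- fv
    if (!is.null(m$label)) labels <- c(labels, as.integer(m$label))
    else if (!is.null(m$truth)) labels <- c(labels, m$truth$class_label)
  }
  list(vectors = vectors,
       labels = if (length(labels) == length(vectors)) labels else NULL,
       excluded = excluded)
}

#' Read a run manifest
#'
#' A manifest is a YAML or JSON file with an optional `config` mapping
#' (see [read_pipeline_config()]) and a `patients` list; each patient
#' has `id`, `face` and `mouth` file paths (relative paths resolve
#' against the manifest's directory) and an optional 0/1 `label`.
#'
#' @param path manifest file path.
#' @return A list with `config`, `patients` (data frame) usable by
#'   [run_pipeline()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE) else
    yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, as.list(raw$config))
  if (length(raw$patients) == 0L) stop("manifest lists no patients")
  base <- dirname(normalizePath(path))
  pat <- do.call(rbind, lapply(raw$patients, function(p) {
    data.frame(id = as.character(p$id),
               face = as.character(p$face), mouth = as.character(p$mouth),
               label = if (is.null(p$label)) NA_integer_
                       else as.integer(p$label))
  }))
  for (col in c("face", "mouth")) {
    rel <- !grepl("^(/|[A-Za-z]:)", pat[[col]])
    pat[[col]][rel] <- file.path(base, pat[[col]][rel])
  }
  missing <- c(pat$face, pat$mouth)[!file.exists(c(pat$face, pat$mouth))]
  if (length(missing) > 0L)
    stop(sprintf("missing input file(s): %s",
                 paste(missing, collapse = ", ")))
  list(config = cfg, patients = pat)
}

#' Run the full pipeline on a manifest of thermogram files
#'
#' For every patient: read both views, detect edges, estimate the
#' symmetry axis, split the field and extract the averaged feature
#' vector; then evaluate the 1-NN classifier with the repeated-split
#' protocol. When `out_dir` is given, the feature matrix
#' (`features.tsv`), the report (`report.txt` plus `report_roc.tsv`)
#' and a `run_info.txt` with every parameter and seed are written
#' there; a rerun with the same manifest and seed reproduces these
#' files byte-identically.
#'
#' @param manifest result of [read_manifest()], or a path to a manifest
#'   file.
#' @param seed integer master seed (defaults to the manifest config's
#'   `rng_seed`).
#' @param out_dir optional output directory.
#' @return The `"classification_report"`, with attributes `features`
#'   (the feature-vector list), `labels` and `excluded`.
#' @export
run_pipeline <- function(manifest, seed = NULL, out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  cfg <- manifest$config
  if (is.null(seed)) seed <- cfg$rng_seed
  pat <- manifest$patients
  if (any(is.na(pat$label)))
    stop("classification requires a 0/1 label for every patient")
  cohort <- lapply(seq_len(nrow(pat)), function(i)
    list(id = pat$id[i],
         face = read_thermogram(pat$face[i], view = "face", config = cfg),
         mouth = read_thermogram(pat$mouth[i], view = "mouth", config = cfg),
         label = pat$label[i]))
  feats <- cohort_features(cohort, cfg, seed = seed)
  ds <- labeled_dataset(feats$vectors, feats$labels)
  report <- evaluate_knn(ds, cfg, seed = seed + 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_matrix(feats$vectors,
                         file.path(out_dir, "features.tsv"),
                         labels = feats$labels)
    write_report(report, file.path(out_dir, "report.txt"))
    info <- c(sprintf("seed: %d", seed),
              sprintf("excluded: %s",
                      if (length(feats$excluded) == 0L) "none"
                      else paste(feats$excluded, collapse = ",")),
              vapply(names(cfg), function(k)
                sprintf("%s: %s", k, format(cfg[[k]])), character(1)))
    writeLines(info, file.path(out_dir, "run_info.txt"))
  }
  attr(report, "features") <- feats$vectors
  attr(report, "labels") <- feats$labels
  attr(report, "excluded") <- feats$excluded
  report
}
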