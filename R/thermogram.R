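#' Construct a thermogram
#'
#' A thermogram is a rectangular grid of surface temperatures in degrees
#' Celsius, as recorded by an infrared camera, together with the view it
#' depicts (full face or open mouth cavity) and an opaque id label.
#'
#' Coordinates throughout the package are 1-based `(row, col)` with row 1 at
#' the image top and pixel centers at integer coordinates.
#'
#' @param values numeric matrix of temperatures, degrees Celsius.
#' @param view one of `"face"` or `"mouth"`.
#' @param id opaque character label for the patient/image.
#' @param min_temp_c,max_temp_c physical plausibility window in degrees
#'   Celsius; defaults to the measurable range of a typical clinical
#'   long-wave infrared camera, -20 to +250.
#' @return An object of class `"thermogram"`: a list with elements
#'   `values`, `view`, `id`.
#' @examples
#' tg <- thermogram(matrix(33, 8, 8), view = "face", id = "demo")
#' dim(tg$values)
#' @export
thermogram <- function(values, view = c("face", "mouth"), id = "unlabeled",
                       min_temp_c = -20, max_temp_c = 250) {
  view <- match.arg(view)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("thermogram must be at least 2x2 pixels")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite temperature at row %d, col %d",
                 bad[1, 1], bad[1, 2]))
  out <- which(values < min_temp_c | values > max_temp_c, arr.ind = TRUE)
  if (nrow(out) > 0L)
    stop(sprintf(
      "temperature %.6g at row %d, col %d outside physical window [%g, %g] C",
      values[out[1, 1], out[1, 2]], out[1, 1], out[1, 2],
      min_temp_c, max_temp_c))
  structure(list(values = values, view = view, id = as.character(id)),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram '%s'> %s view, %d x %d px, %.2f-%.2f C\n",
              x$id, x$view, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Display a thermogram as a temperature map
#'
#' Visualization only; uses a conventional thermal palette with row 1 at
#' the top.
#'
#' @param x a [thermogram()].
#' @param ... passed to [graphics::image()].
#' @export
plot.thermogram <- function(x, ...) {
  v <- x$values
  # image() draws x along rows; transpose and flip so row 1 is on top
  graphics::image(t(v)[, nrow(v):1, drop = FALSE],
                  col = grDevices::hcl.colors(64, "Inferno"),
                  axes = FALSE, asp = nrow(v) / ncol(v),
                  main = sprintf("%s (%s)", x$id, x$view), ...)
  invisible(x)
}

#' Read a thermogram from a delimited text file
#'
#' The file holds one image row per line, values in degrees Celsius
#' separated by commas and/or whitespace. Lines starting with `#` form an
#' optional key-value header (`# id: ...`, `# view: ...`); an explicit
#' `view` argument overrides the header.
#'
#' @param path path to the matrix file.
#' @param view `"face"`, `"mouth"`, or `NULL` to take the view from the
#'   file header (defaulting to `"face"`).
#' @param config a [pipeline_config()]; supplies the physical temperature
#'   window used for validation.
#' @return A validated [thermogram()].
#' @export
read_thermogram <- function(path, view = NULL, config = pipeline_config()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*\\S)", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop(sprintf("no data rows in %s", path))
  fields <- strsplit(trimws(body), "[,[:space:]]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged rows in %s: row %d has %d fields, row 1 has %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(nf[1])))
  values <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop(sprintf("non-numeric field at row %d, col %d in %s",
                 bad[1, 1], bad[1, 2], path))
  }
  if (is.null(view)) view <- meta$view %||% "face"
  id <- meta$id %||% sub("\\.[A-Za-z0-9]+$", "", basename(path))
  thermogram(values, view = view, id = id,
             min_temp_c = config$min_temp_c, max_temp_c = config$max_temp_c)
}

#' Write a thermogram to a delimited text file
#'
#' Values are written with six decimal places, one image row per line,
#' comma-separated, after a two-line `# id:` / `# view:` header. The file
#' round-trips through [read_thermogram()]: rewriting the re-read
#' thermogram reproduces the text fields exactly.
#'
#' @param tg a [thermogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  if (any(!is.finite(tg$values)))
    stop("refusing to write thermogram with non-finite values")
  rows <- apply(tg$values, 1L, function(r)
    paste(sprintf("%.6f", r), collapse = ","))
  writeLines(c(sprintf("# id: %s", tg$id),
               sprintf("# view: %s", tg$view), rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
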