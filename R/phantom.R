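#' Specification of a synthetic thermogram phantom
#'
#' Phantoms emulate the acquisition conditions of a clinical facial
#' thermography protocol: a bilaterally symmetric elliptical "face" of
#' warm skin over a uniform ambient background, additive Gaussian sensor
#' noise at the thermal-sensitivity scale of a clinical long-wave camera
#' (sd 0.06 C), and an optional unilateral hot-spot lesion modeled as an
#' isotropic Gaussian bump.
#'
#' The face is an ellipse with semiaxis `face_semiaxes[1]` along the
#' symmetry axis (nominally vertical, tilted by `axis_angle_deg`) and
#' `face_semiaxes[2]` across it. Inside the face the temperature falls
#' off quadratically from `skin_base_c` at the center by
#' `radial_gradient_c` at the rim, which is mirror-symmetric about the
#' axis by construction.
#'
#' @param shape integer `(n_rows, n_cols)`; default `c(240, 320)`, the
#'   nominal sensor resolution.
#' @param face_center `(row, col)` of the face ellipse center.
#' @param face_semiaxes `(along-axis, across-axis)` semiaxes in pixels;
#'   the along-axis value must be the larger so the fitted major axis is
#'   the symmetry axis.
#' @param axis_angle_deg tilt of the symmetry axis from vertical,
#'   degrees; positive tilts the lower end toward higher columns.
#' @param skin_base_c skin temperature at the face center, C.
#' @param ambient_c background temperature, C (controlled room, ~22 C).
#' @param radial_gradient_c center-to-rim temperature drop, C.
#' @param noise_sd_c sd of i.i.d. Gaussian sensor noise, C.
#' @param lesion_amp_c peak amplitude of the lesion bump, C; 0 means no
#'   lesion.
#' @param lesion_center `(row, col)` of the lesion peak; required when
#'   `lesion_amp_c > 0`, must lie inside the face ellipse and strictly
#'   off the symmetry axis.
#' @param lesion_radius_px lesion extent in pixels, read as twice the
#'   Gaussian sd.
#' @param mouth_base_c temperature at the mouth-cavity center in the
#'   open-mouth view, C; warmer than the surrounding skin.
#' @param seed integer seed driving the noise field.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(240L, 320L),
                         face_center = c(120, 160),
                         face_semiaxes = c(90, 65),
                         axis_angle_deg = 0,
                         skin_base_c = 33.0,
                         ambient_c = 22.0,
                         radial_gradient_c = 1.5,
                         noise_sd_c = 0.06,
                         lesion_amp_c = 0,
                         lesion_center = NULL,
                         lesion_radius_px = 8,
                         mouth_base_c = 35.5,
                         seed = 1L) {
  spec <- structure(list(shape = as.integer(shape),
                         face_center = as.numeric(face_center),
                         face_semiaxes = as.numeric(face_semiaxes),
                         axis_angle_deg = as.numeric(axis_angle_deg),
                         skin_base_c = skin_base_c, ambient_c = ambient_c,
                         radial_gradient_c = radial_gradient_c,
                         noise_sd_c = noise_sd_c,
                         lesion_amp_c = lesion_amp_c,
                         lesion_center = if (is.null(lesion_center)) NULL
                                         else as.numeric(lesion_center),
                         lesion_radius_px = as.numeric(lesion_radius_px),
                         mouth_base_c = mouth_base_c,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$noise_sd_c < 0) stop("noise_sd_c must be >= 0")
  if (spec$lesion_amp_c < 0) stop("lesion_amp_c must be >= 0")
  a <- spec$face_semiaxes[1]; b <- spec$face_semiaxes[2]
  if (a <= 0 || b <= 0) stop("face semiaxes must be positive")
  if (a < b) stop("along-axis semiaxis must be >= across-axis semiaxis")
  th <- spec$axis_angle_deg * pi / 180
  half_r <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  half_c <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  ctr <- spec$face_center
  if (ctr[1] - half_r < 1.5 || ctr[1] + half_r > spec$shape[1] - 0.5 ||
      ctr[2] - half_c < 1.5 || ctr[2] + half_c > spec$shape[2] - 0.5)
    stop("face ellipse does not fit inside the image")
  if (spec$lesion_amp_c > 0) {
    if (is.null(spec$lesion_center))
      stop("lesion_amp_c > 0 requires a lesion_center")
    fr <- ellipse_frame(spec)
    lc <- ellipse_coords(spec$lesion_center[1], spec$lesion_center[2], fr)
    if (lc$rho2 >= 1) stop("lesion center outside face ellipse")
    if (abs(lc$t) < 1e-9)
      stop("lesion center must lie strictly on one side of the axis")
    if (spec$lesion_radius_px <= 0) stop("lesion_radius_px must be positive")
  }
  invisible(spec)
}

# Axis-aligned frame of the face ellipse: unit axis direction d (row, col)
# and its perpendicular n, plus center and semiaxes.
ellipse_frame <- function(spec) {
  th <- spec$axis_angle_deg * pi / 180
  d <- c(cos(th), sin(th))
  list(center = spec$face_center, d = d, n = c(-d[2], d[1]),
       a = spec$face_semiaxes[1], b = spec$face_semiaxes[2])
}

# Along-axis (s), across-axis (t) coordinates and normalized squared
# elliptical radius of points (r, c) in a frame; vectorized.
ellipse_coords <- function(r, c, fr, center = fr$center,
                           a = fr$a, b = fr$b) {
  dr <- r - center[1]; dc <- c - center[2]
  s <- dr * fr$d[1] + dc * fr$d[2]
  t <- dr * fr$n[1] + dc * fr$n[2]
  list(s = s, t = t, rho2 = (s / a)^2 + (t / b)^2)
}

# Geometry of the open mouth cavity derived from the face frame: an
# ellipse elongated along the facial axis, centered below the face center.
mouth_geometry <- function(spec) {
  fr <- ellipse_frame(spec)
  list(center = fr$center + 0.35 * fr$a * fr$d,
       a = 0.40 * fr$a, b = 0.28 * fr$b)
}

# Noiseless face field plus lesion bump; returns matrix and face mask.
phantom_field <- function(spec, mouth = FALSE) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  fr <- ellipse_frame(spec)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ec <- ellipse_coords(rr, cc, fr)
  vals <- matrix(spec$ambient_c, nr, nc)
  face <- ec$rho2 <= 1
  vals[face] <- spec$skin_base_c - spec$radial_gradient_c * ec$rho2[face]
  mouth_mask <- NULL
  if (mouth) {
    mg <- mouth_geometry(spec)
    em <- ellipse_coords(rr, cc, fr, center = mg$center, a = mg$a, b = mg$b)
    mouth_mask <- em$rho2 <= 1
    vals[mouth_mask] <- spec$mouth_base_c - 0.3 * em$rho2[mouth_mask]
  }
  if (spec$lesion_amp_c > 0) {
    sdl <- spec$lesion_radius_px / 2
    d2 <- (rr - spec$lesion_center[1])^2 + (cc - spec$lesion_center[2])^2
    vals <- vals + spec$lesion_amp_c * exp(-d2 / (2 * sdl^2))
  }
  list(values = vals, face_mask = face, mouth_mask = mouth_mask)
}

phantom_truth <- function(spec) {
  fr <- ellipse_frame(spec)
  side <- "none"
  if (spec$lesion_amp_c > 0) {
    t <- ellipse_coords(spec$lesion_center[1], spec$lesion_center[2], fr)$t
    side <- if (t < 0) "left" else "right"
  }
  structure(list(axis_point = fr$center, axis_direction = fr$d,
                 has_lesion = spec$lesion_amp_c > 0, lesion_side = side,
                 class_label = as.integer(spec$lesion_amp_c > 0)),
            class = "phantom_truth")
}

phantom_make <- function(spec, mouth, id) {
  validate_phantom_spec(spec)
  f <- phantom_field(spec, mouth = mouth)
  vals <- f$values
  if (spec$noise_sd_c > 0)
    vals <- vals + with_seed(spec$seed,
      matrix(stats::rnorm(length(vals), 0, spec$noise_sd_c),
             nrow(vals), ncol(vals)))
  list(thermogram = thermogram(vals, view = if (mouth) "mouth" else "face",
                               id = id),
       truth = phantom_truth(spec))
}

#' Generate a synthetic face thermogram with known ground truth
#'
#' @param spec a [phantom_spec()].
#' @param id id label for the resulting thermogram.
#' @return A list with elements `thermogram` (a [thermogram()]) and
#'   `truth` (axis point/direction, lesion side, class label; class
#'   label is 1 exactly when a lesion is present).
#' @examples
#' ph <- make_face_phantom(phantom_spec(noise_sd_c = 0))
#' range(ph$thermogram$values)
#' @export
make_face_phantom <- function(spec, id = "phantom") {
  phantom_make(spec, mouth = FALSE, id = id)
}

#' Generate a synthetic open-mouth thermogram with known ground truth
#'
#' As [make_face_phantom()], plus a smaller interior mouth-cavity
#' ellipse, elongated along the symmetry axis and warmer
#' (`mouth_base_c`) than the surrounding skin, as in an open-mouth
#' frontal projection.
#'
#' @inheritParams make_face_phantom
#' @return A list with elements `thermogram` and `truth`.
#' @export
make_mouth_phantom <- function(spec, id = "phantom") {
  phantom_make(spec, mouth = TRUE, id = id)
}

#' Generate a labeled synthetic cohort of face and mouth thermograms
#'
#' Builds `n_nt` lesion-free (non-tumor, label 0) and `n_t` lesioned
#' (tumor, label 1) members. Each member gets a randomized axis tilt
#' (uniform in -10..10 degrees); lesioned members get a lesion of peak
#' amplitude `lesion_amp_c` on a randomly chosen side, placed on the
#' facial skin in the face view and inside the mouth cavity in the mouth
#' view. Per-member noise seeds are derived deterministically from
#' `seed`, so the whole cohort reproduces bit-for-bit.
#'
#' @param n_nt,n_t members per class, each >= 1 (n_t may be 0).
#' @param base_spec a [phantom_spec()] supplying the shared geometry,
#'   temperatures, noise level and lesion radius.
#' @param lesion_amp_c lesion peak amplitude for the tumor class, C.
#' @param seed integer cohort seed.
#' @return A list of members, each a list with `id`, `face`, `mouth`
#'   (thermograms), and `truth`.
#' @export
make_cohort <- function(n_nt, n_t, base_spec = phantom_spec(),
                        lesion_amp_c = 1.0, seed = 1L) {
  if (n_nt < 1L || n_t < 0L) stop("need n_nt >= 1 and n_t >= 0")
  n <- n_nt + n_t
  fr <- ellipse_frame(base_spec)
  mg <- mouth_geometry(base_spec)
  with_seed(seed, {
    noise_seeds <- matrix(sample.int(2147483646L, 2L * n), ncol = 2L)
    lapply(seq_len(n), function(i) {
      tumor <- i > n_nt
      id <- if (tumor) sprintf("T%02d", i - n_nt) else sprintf("NT%02d", i)
      angle <- stats::runif(1, -10, 10)
      sp <- base_spec
      sp$axis_angle_deg <- angle
      fri <- ellipse_frame(sp)
      face_sp <- sp; mouth_sp <- sp
      if (tumor) {
        side <- sample(c(-1, 1), 1L)
        sf <- stats::runif(1, -0.35, 0.35); tf <- side * stats::runif(1, 0.25, 0.55)
        face_sp$lesion_amp_c <- lesion_amp_c
        face_sp$lesion_center <- fri$center + sf * fri$a * fri$d +
          tf * fri$b * fri$n
        mgi <- mouth_geometry(sp)
        sm <- stats::runif(1, -0.45, 0.45); tm <- side * stats::runif(1, 0.30, 0.65)
        mouth_sp$lesion_amp_c <- lesion_amp_c
        mouth_sp$lesion_center <- mgi$center + sm * mgi$a * fri$d +
          tm * mgi$b * fri$n
      } else {
        # consume the same number of draws as the tumor branch so a
        # member's geometry depends only on its position, not its class
        invisible(c(sample(c(-1, 1), 1L), stats::runif(4)))
      }
      face_sp$seed <- noise_seeds[i, 1]
      mouth_sp$seed <- noise_seeds[i, 2]
      fp <- make_face_phantom(face_sp, id = id)
      mp <- make_mouth_phantom(mouth_sp, id = id)
      # `label` is the cohort-group assignment; it equals
      # truth$class_label whenever lesion_amp_c > 0, but stays 1 for
      # tumor-group members of a null cohort (lesion_amp_c = 0), where
      # the two groups differ in nothing but the label
      list(id = id, face = fp$thermogram, mouth = mp$thermogram,
           truth = fp$truth, label = as.integer(tumor))
    })
  })
}

#' Write a phantom cohort to a directory
#'
#' One face file and one mouth file per member (delimited text, see
#' [write_thermogram()]) plus a tab-separated `truth.tsv` with the id,
#' class label, lesion side and true-axis parameters of every member.
#'
#' @param cohort output of [make_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- do.call(rbind, lapply(cohort, function(m) {
    write_thermogram(m$face, file.path(dir, sprintf("%s_face.txt", m$id)))
    write_thermogram(m$mouth, file.path(dir, sprintf("%s_mouth.txt", m$id)))
    data.frame(id = m$id, label = m$label %||% m$truth$class_label,
               lesion_side = m$truth$lesion_side,
               axis_row = m$truth$axis_point[1],
               axis_col = m$truth$axis_point[2],
               axis_dir_row = m$truth$axis_direction[1],
               axis_dir_col = m$truth$axis_direction[2])
  }))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
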