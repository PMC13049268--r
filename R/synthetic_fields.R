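#' Configuration of a synthetic pTx head-model cohort
#'
#' Parameters of the synthetic multi-subject B1+/deltaB0 generator that
#' emulates a universal-pulse design database: an 8-channel loop array on a
#' ring around an ellipsoidal head, smooth off-resonance plus localized
#' hotspots near the air cavities (frontal sinus, ear canals), and
#' per-subject anatomical/loading jitter.
#'
#' @param n_subjects Cohort size (default 20).
#' @param grid_dim Voxel grid dimensions (x, y, z).
#' @param spacing_mm Isotropic voxel spacing (mm).
#' @param head_semiaxes_mm Ellipsoid semi-axes (mm): left-right,
#'   posterior-anterior, inferior-superior.
#' @param coil_radius_mm Radius of the transmit-loop ring (mm).
#' @param ref_sens_hz_per_v Per-channel sensitivity magnitude at the head
#'   centre (Hz/V).
#' @param sens_decay Exponent of the magnitude decay with distance from
#'   each loop.
#' @param rf_wavelength_mm In-tissue RF wavelength driving the propagation
#'   phase (mm); ~130 mm at 297 MHz gives the 7T centre-bright CP mode.
#' @param db0_smooth_hz Amplitude bound of the smooth off-resonance term.
#' @param db0_hotspot_hz Peak amplitude of the cavity hotspots (Hz).
#' @param hotspot_sigma_mm Gaussian width of the hotspots (mm).
#' @param jitter_size,jitter_pos_mm,jitter_tilt_rad,jitter_load Relative
#'   head-size, head-position (mm), head-tilt (rad) and coil-loading
#'   inter-subject variation scales.
#' @param n_channels Number of transmit channels.
#' @param master_seed Master seed; the full cohort is a pure function of
#'   this configuration.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20L,
                          grid_dim = c(24L, 20L, 20L),
                          spacing_mm = 5,
                          head_semiaxes_mm = c(55, 45, 40),
                          coil_radius_mm = 135,
                          ref_sens_hz_per_v = 11.75,
                          sens_decay = 1.5,
                          rf_wavelength_mm = 130,
                          db0_smooth_hz = 150,
                          db0_hotspot_hz = 600,
                          hotspot_sigma_mm = 16,
                          jitter_size = 0.05,
                          jitter_pos_mm = 4,
                          jitter_tilt_rad = 0.07,
                          jitter_load = 0.10,
                          n_channels = 8L,
                          master_seed = 42L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  if (any(grid_dim < 2)) stop("degenerate grid")
  structure(list(
    n_subjects = as.integer(n_subjects), grid_dim = as.integer(grid_dim),
    spacing_mm = spacing_mm, head_semiaxes_mm = head_semiaxes_mm,
    coil_radius_mm = coil_radius_mm,
    ref_sens_hz_per_v = ref_sens_hz_per_v, sens_decay = sens_decay,
    rf_wavelength_mm = rf_wavelength_mm,
    db0_smooth_hz = db0_smooth_hz, db0_hotspot_hz = db0_hotspot_hz,
    hotspot_sigma_mm = hotspot_sigma_mm,
    jitter_size = jitter_size, jitter_pos_mm = jitter_pos_mm,
    jitter_tilt_rad = jitter_tilt_rad, jitter_load = jitter_load,
    n_channels = as.integer(n_channels),
    master_seed = as.integer(master_seed)), class = "cohort_config")
}

# small rotation matrix from tilt angles about x and y
.tilt_matrix <- function(ax, ay) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  ry %*% rx
}

#' Generate one synthetic subject field map
#'
#' Deterministic in `(config, subject_index)`. The head is an ellipsoid
#' with jittered size, position and tilt; channel sensitivities stem from
#' loop-like sources on a ring with magnitude decaying with source distance
#' and a propagation phase advancing with distance, phase-referenced to the
#' CP mode so that the CP combination `|sum_c s_c|` is centre-bright;
#' deltaB0 is a smooth low-order polynomial plus Gaussian hotspots at the
#' anterior-inferior (sinus) and lateral-inferior (ear canal) mask
#' boundary.
#'
#' @param config A [cohort_config()].
#' @param subject_index Subject number (1-based).
#' @return Object of class `subject_fieldmap` with full-grid arrays
#'   `sens` (nx, ny, nz, n_channels; complex Hz/V), `db0` (Hz), `mask`
#'   (logical), plus `dim`, `spacing_mm`, `origin_mm`, `subject_id`,
#'   `seed`.
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(config$grid_dim < 2)) stop("degenerate grid")
  seed <- config$master_seed + 7919L * as.integer(subject_index)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  nd <- config$grid_dim
  sp <- config$spacing_mm
  ax <- lapply(nd, function(n) (seq_len(n) - (n + 1) / 2) * sp)
  origin <- vapply(ax, `[`, numeric(1), 1)
  pos <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))

  semi <- config$head_semiaxes_mm * (1 + config$jitter_size * rnorm(3))
  center <- config$jitter_pos_mm * rnorm(3)
  rot <- .tilt_matrix(config$jitter_tilt_rad * rnorm(1),
                      config$jitter_tilt_rad * rnorm(1))
  rel <- sweep(pos, 2, center) %*% rot
  mask_v <- rowSums(sweep(rel, 2, semi, "/")^2) <= 1
  if (!any(mask_v)) stop("mask is empty; check grid and head size")

  nc <- config$n_channels
  theta <- 2 * pi * (seq_len(nc) - 1) / nc
  coil_xy <- config$coil_radius_mm * cbind(cos(theta), sin(theta), 0)
  load <- 1 + config$jitter_load * rnorm(nc)
  ph_jit <- 0.15 * rnorm(nc)
  k_prop <- 2 * pi / config$rf_wavelength_mm
  nv <- nrow(pos)
  sens_v <- matrix(0i, nv, nc)
  for (c in seq_len(nc)) {
    d <- sqrt(rowSums(sweep(pos, 2, coil_xy[c, ] + center)^2))
    mag <- load[c] * config$ref_sens_hz_per_v *
      (config$coil_radius_mm / pmax(d, 20))^config$sens_decay
    # phase referenced to CP mode: the azimuthal drive phase is absorbed,
    # only the propagation phase (and a small channel offset) remains
    sens_v[, c] <- mag * exp(-1i * (k_prop * (d - config$coil_radius_mm) +
                                      ph_jit[c]))
  }

  # smooth low-order polynomial off-resonance, scaled to the configured bound
  u <- sweep(rel, 2, semi, "/")
  cf <- rnorm(9)
  raw <- cf[1] + cf[2] * u[, 1] + cf[3] * u[, 2] + cf[4] * u[, 3] +
    cf[5] * u[, 1] * u[, 2] + cf[6] * u[, 2] * u[, 3] +
    cf[7] * u[, 1]^2 + cf[8] * u[, 2]^2 + cf[9] * u[, 3]^2
  db0_v <- config$db0_smooth_hz * raw / max(abs(raw[mask_v]), 1e-9)

  hot_centers <- rbind(c(0, 0.85, -0.55),      # frontal sinus
                       c(0.90, 0, -0.45),      # right ear canal
                       c(-0.90, 0, -0.45))     # left ear canal
  hot_sign <- c(1, -1, -1)
  for (h in seq_len(nrow(hot_centers))) {
    hc <- center + as.vector((hot_centers[h, ] * semi) %*% t(rot))
    amp <- config$db0_hotspot_hz * runif(1, 0.7, 1.0) * hot_sign[h]
    d2 <- rowSums(sweep(pos, 2, hc)^2)
    db0_v <- db0_v + amp * exp(-d2 / (2 * config$hotspot_sigma_mm^2))
  }

  structure(list(
    subject_id = sprintf("sub-%02d", as.integer(subject_index)),
    seed = seed, dim = nd, spacing_mm = sp, origin_mm = origin,
    n_channels = nc,
    sens = array(sens_v, dim = c(nd, nc)),
    db0 = array(db0_v, dim = nd),
    mask = array(mask_v, dim = nd)), class = "subject_fieldmap")
}

#' @export
print.subject_fieldmap <- function(x, ...) {
  cat(sprintf(
    "<subject_fieldmap> %s: %s grid @ %.3g mm, %d channels, %d masked voxels\n",
    x$subject_id, paste(x$dim, collapse = "x"), x$spacing_mm,
    x$n_channels, sum(x$mask)))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return List of [generate_subject()] results, length `n_subjects`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(seq_len(config$n_subjects), function(i) generate_subject(config, i))
}

#' Masked-voxel view of a subject field map
#'
#' @param sfm A [generate_subject()] result.
#' @return List with `sens` (complex Nv x Nc), `db0` (Nv), `pos` (Nv x 3,
#'   mm) restricted to the brain mask, plus `idx` (linear grid indices).
#' @export
fieldmap_voxels <- function(sfm) {
  stopifnot(inherits(sfm, "subject_fieldmap"))
  nd <- sfm$dim
  idx <- which(as.vector(sfm$mask))
  ax <- lapply(seq_along(nd), function(a)
    sfm$origin_mm[a] + (seq_len(nd[a]) - 1) * sfm$spacing_mm)
  pos <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))[idx, ,
                                                                      drop = FALSE]
  sens <- matrix(as.vector(sfm$sens), prod(nd), sfm$n_channels)[idx, ,
                                                                drop = FALSE]
  list(sens = sens, db0 = as.vector(sfm$db0)[idx], pos = pos, idx = idx)
}

# NIfTI affine for a subject grid (scanner frame, isocenter origin)
.fieldmap_affine <- function(sfm) {
  aff <- diag(4)
  aff[1, 1] <- aff[2, 2] <- aff[3, 3] <- sfm$spacing_mm
  aff[1:3, 4] <- sfm$origin_mm
  aff
}

.write_vol <- function(arr, sfm, path) {
  im <- RNifti::asNifti(arr * 1.0)
  im <- RNifti::`sform<-`(im, structure(.fieldmap_affine(sfm), code = 2L))
  RNifti::writeNifti(im, path)
}

#' Write / read a subject field map as NIfTI volumes
#'
#' One volume per channel real and imaginary part
#' (`sens_ch01_real.nii.gz`, ...), one for deltaB0 (`db0.nii.gz`), one for
#' the mask (`mask.nii.gz`), plus a `subject.json` with scalar metadata.
#' The NIfTI affine encodes the voxel positions (scanner frame, isocenter
#' origin). `read_fieldmap(write_fieldmap(x))` is the identity to float
#' precision.
#'
#' @param sfm A [generate_subject()] result.
#' @param dir Output directory (created if missing).
#' @return `write_fieldmap` returns `dir` invisibly; `read_fieldmap`
#'   returns a `subject_fieldmap`.
#' @export
write_fieldmap <- function(sfm, dir) {
  stopifnot(inherits(sfm, "subject_fieldmap"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (c in seq_len(sfm$n_channels)) {
    sl <- sfm$sens[, , , c]
    .write_vol(Re(sl), sfm, file.path(dir, sprintf("sens_ch%02d_real.nii.gz", c)))
    .write_vol(Im(sl), sfm, file.path(dir, sprintf("sens_ch%02d_imag.nii.gz", c)))
  }
  .write_vol(sfm$db0, sfm, file.path(dir, "db0.nii.gz"))
  .write_vol(sfm$mask * 1.0, sfm, file.path(dir, "mask.nii.gz"))
  meta <- list(subject_id = sfm$subject_id, seed = sfm$seed,
               n_channels = sfm$n_channels, spacing_mm = sfm$spacing_mm,
               dim = sfm$dim, origin_mm = sfm$origin_mm)
  writeLines(jsonlite::toJSON(meta, digits = I(17), auto_unbox = TRUE),
             file.path(dir, "subject.json"))
  invisible(dir)
}

.read_vol <- function(path, expect_dim = NULL) {
  if (!file.exists(path)) stop("missing field-map file: ", path)
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (!is.null(expect_dim) && !identical(dim(arr), as.integer(expect_dim)))
    stop(sprintf("inconsistent shape in %s: got %s, expected %s", path,
                 paste(dim(arr), collapse = "x"),
                 paste(expect_dim, collapse = "x")))
  list(arr = arr, affine = RNifti::xform(im))
}

#' @rdname write_fieldmap
#' @export
read_fieldmap <- function(dir) {
  meta_path <- file.path(dir, "subject.json")
  if (!file.exists(meta_path)) stop("missing field-map file: ", meta_path)
  meta <- jsonlite::fromJSON(meta_path)
  nd <- as.integer(meta$dim)
  nc <- as.integer(meta$n_channels)
  v0 <- .read_vol(file.path(dir, "db0.nii.gz"), nd)
  aff <- v0$affine
  sens <- array(0i, dim = c(nd, nc))
  for (c in seq_len(nc)) {
    re <- .read_vol(file.path(dir, sprintf("sens_ch%02d_real.nii.gz", c)), nd)
    im <- .read_vol(file.path(dir, sprintf("sens_ch%02d_imag.nii.gz", c)), nd)
    sens[, , , c] <- re$arr + 1i * im$arr
  }
  mk <- .read_vol(file.path(dir, "mask.nii.gz"), nd)
  structure(list(
    subject_id = meta$subject_id, seed = meta$seed, dim = nd,
    spacing_mm = aff[1, 1], origin_mm = as.vector(aff[1:3, 4]),
    n_channels = nc, sens = sens, db0 = v0$arr,
    mask = array(mk$arr > 0.5, dim = nd)), class = "subject_fieldmap")
}

#' Write / read a cohort with a manifest
#'
#' Serializes every subject into `dir/sub-XX/` and emits
#' `dir/manifest.json` listing subject directories and seeds.
#'
#' @param cohort List of `subject_fieldmap` objects.
#' @param dir Output directory.
#' @return `write_cohort` returns the manifest path invisibly;
#'   `read_cohort` returns the list of subjects.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(s) {
    write_fieldmap(s, file.path(dir, s$subject_id))
    list(subject_id = s$subject_id, path = s$subject_id, seed = s$seed)
  })
  mp <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(list(format = "ptxgrape-cohort-1",
                                   subjects = entries),
                              digits = I(17), auto_unbox = TRUE), mp)
  invisible(mp)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("missing cohort manifest: ", mp)
  man <- jsonlite::fromJSON(mp, simplifyDataFrame = FALSE)
  lapply(man$subjects, function(e) read_fieldmap(file.path(dir, e$path)))
}
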