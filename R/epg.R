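#' EPG configuration for a (variable-flip-angle) TSE train
#'
#' Describes the refocusing train of a turbo-spin-echo sequence for
#' extended-phase-graph simulation: flip angles and phases of the
#' refocusing pulses, echo spacings (the first spacing may differ from the
#' rest, e.g. when the excitation pulse length delays the first
#' refocusing pulse), relaxation times and the echo to report.
#'
#' @param flips_deg Refocusing flip angles (deg, in \[0, 180\]).
#' @param phases_rad Refocusing phases (rad); scalar is recycled.
#' @param esp_ms Echo spacings (ms): time from excitation to echo 1, then
#'   between consecutive echoes; scalar is recycled.
#' @param t1_ms,t2_ms Relaxation times (ms); `Inf` disables relaxation.
#' @param target_echo Echo index reported by [signal_map()] ("central
#'   echo" of the acquisition).
#' @return Object of class `epg_config`.
#' @export
epg_config <- function(flips_deg, phases_rad = 0, esp_ms = 6.65,
                       t1_ms = 1500, t2_ms = 60,
                       target_echo = ceiling(length(flips_deg) / 2)) {
  n <- length(flips_deg)
  if (!n) stop("empty refocusing train")
  if (any(flips_deg < 0 | flips_deg > 180))
    stop("refocusing flips must lie in [0, 180] degrees")
  esp <- rep_len(esp_ms, n)
  if (any(esp <= 0)) stop("echo spacings must be positive")
  structure(list(flips_deg = flips_deg,
                 phases_rad = rep_len(phases_rad, n),
                 esp_ms = esp, t1_ms = t1_ms, t2_ms = t2_ms,
                 target_echo = as.integer(target_echo)),
            class = "epg_config")
}

#' Default variable-flip-angle TSE refocusing train
#'
#' A 107-echo train: one initial 180 degree refocusing pulse, then a
#' smooth exponential ramp from 120 degrees down to a 55 degree plateau
#' (a typical T2-weighted vFA shape). All refocusing phases are 0; a
#' CPMG-compliant excitation then uses phase `-pi/2`. Echo spacing
#' 6.65 ms with a first spacing of 12.5 ms.
#'
#' @param n_echoes Train length.
#' @param esp_ms Steady echo spacing (ms).
#' @param first_esp_ms First echo spacing (ms).
#' @param ... Passed to [epg_config()] (e.g. `t1_ms`, `t2_ms`).
#' @return An [epg_config()].
#' @export
default_vfa_train <- function(n_echoes = 107L, esp_ms = 6.65,
                              first_esp_ms = 12.5, ...) {
  ramp <- pmax(55, 120 * exp(-(seq_len(n_echoes - 1) - 1) / 18))
  epg_config(flips_deg = c(180, ramp), phases_rad = 0,
             esp_ms = c(first_esp_ms, rep(esp_ms, n_echoes - 1)), ...)
}

#' Read / write a refocusing-train specification file
#'
#' Plain delimited text with columns `flip_deg`, `phase_rad`, `esp_ms`.
#'
#' @param path File path.
#' @param cfg An [epg_config()] (for writing).
#' @param ... Passed to [epg_config()] when reading (relaxation times,
#'   target echo).
#' @return `read_train` returns an [epg_config()].
#' @export
read_train <- function(path, ...) {
  d <- utils::read.table(path, header = TRUE)
  epg_config(flips_deg = d$flip_deg, phases_rad = d$phase_rad,
             esp_ms = d$esp_ms, ...)
}

#' @rdname read_train
#' @export
write_train <- function(cfg, path) {
  utils::write.table(
    data.frame(flip_deg = cfg$flips_deg, phase_rad = cfg$phases_rad,
               esp_ms = cfg$esp_ms),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# EPG over a batch of voxels.  States are configuration orders k = 0..K-1:
# Fp[, k+1] = F+(k), Fm[, k+1] = conj(F(-k)), Z[, k+1] = Z(k).
# Each echo period: relax esp/2, unit dephasing shift, RF mixing,
# relax esp/2, shift, read the echo from F+(0).
.epg_batch <- function(exc_fa_deg, exc_phase_rad, cfg) {
  nv <- length(exc_fa_deg)
  ne <- length(cfg$flips_deg)
  K <- 2L * ne + 2L
  Fp <- matrix(0i, nv, K)
  Fm <- matrix(0i, nv, K)
  Z <- matrix(0i, nv, K)
  Z[, 1] <- 1

  # RF mixing for a rotation consistent with the hard-pulse Bloch kernel:
  # a pulse of phase phi rotates about the axis (-cos phi, -sin phi, 0),
  # so excitation from equilibrium yields Mxy = i * sin(alpha) * e^(i phi)
  mix <- function(alpha_rad, phi) {
    ca2 <- cos(alpha_rad / 2)^2
    sa2 <- sin(alpha_rad / 2)^2
    sa <- sin(alpha_rad)
    list(
      pp = ca2, pm = exp(2i * phi) * sa2, pz = 1i * exp(1i * phi) * sa,
      mp = exp(-2i * phi) * sa2, mm = ca2, mz = -1i * exp(-1i * phi) * sa,
      zp = 0.5i * exp(-1i * phi) * sa, zm = -0.5i * exp(1i * phi) * sa,
      zz = cos(alpha_rad))
  }
  apply_rf <- function(m) {
    Fp2 <- m$pp * Fp + m$pm * Fm + m$pz * Z
    Fm2 <- m$mp * Fp + m$mm * Fm + m$mz * Z
    Z2 <- m$zp * Fp + m$zm * Fm + m$zz * Z
    Fp <<- Fp2; Fm <<- Fm2; Z <<- Z2
  }
  relax <- function(tau_ms) {
    e2 <- if (is.finite(cfg$t2_ms)) exp(-tau_ms / cfg$t2_ms) else 1
    e1 <- if (is.finite(cfg$t1_ms)) exp(-tau_ms / cfg$t1_ms) else 1
    Fp <<- Fp * e2
    Fm <<- Fm * e2
    Z <<- Z * e1
    Z[, 1] <<- Z[, 1] + (1 - e1)
  }
  shift <- function() {
    Fp2 <- cbind(Conj(Fm[, 2]), Fp[, -K, drop = FALSE])
    Fm2 <- cbind(Fm[, -1, drop = FALSE], 0i)
    Fp <<- Fp2
    Fm <<- Fm2
  }

  # excitation: RF rotation applied per voxel (voxel-specific FA/phase)
  a <- exc_fa_deg * pi / 180
  phiv <- exc_phase_rad
  sa <- sin(a)
  Fp[, 1] <- 1i * exp(1i * phiv) * sa * Z[, 1]
  Fm[, 1] <- -1i * exp(-1i * phiv) * sa * Z[, 1]
  Z[, 1] <- cos(a) * Z[, 1]

  echoes <- matrix(0i, nv, ne)
  for (e in seq_len(ne)) {
    half <- cfg$esp_ms[e] / 2
    relax(half)
    shift()
    apply_rf(mix(cfg$flips_deg[e] * pi / 180, cfg$phases_rad[e]))
    relax(half)
    shift()
    echoes[, e] <- Fp[, 1]
  }
  echoes
}

#' Extended-phase-graph simulation of one excitation
#'
#' Standard EPG: the excitation populates the transverse configuration
#' states from equilibrium, and every echo period applies relaxation over
#' the two halves of the echo spacing, unit dephasing shifts, and the RF
#' mixing matrix of the refocusing pulse; echo amplitudes are read from
#' the zero-order transverse state. The CPMG condition requires the
#' excited transverse magnetization to lie along the refocusing rotation
#' axis; in this package's rotation convention that means an excitation
#' phase of `phases_rad - pi/2` (e.g. `-pi/2` for refocusing about
#' phase 0).
#'
#' @param exc_fa_deg Excitation flip angle (deg).
#' @param exc_phase_rad Excitation phase (rad).
#' @param cfg An [epg_config()].
#' @return Object of class `echo_train`: complex echo amplitudes (unit
#'   M0).
#' @export
epg_simulate <- function(exc_fa_deg, exc_phase_rad, cfg) {
  stopifnot(inherits(cfg, "epg_config"))
  structure(as.vector(.epg_batch(exc_fa_deg, exc_phase_rad, cfg)),
            class = "echo_train")
}

#' Per-voxel central-echo signal map
#'
#' Runs the EPG simulation for every voxel of a flip-angle/phase map pair
#' and returns the magnitude of the target echo.
#'
#' @param exc_fa_map Excitation flip angles (deg), any shape.
#' @param exc_phase_map Excitation phases (rad), same shape.
#' @param cfg An [epg_config()].
#' @return Array of echo magnitudes with the shape of `exc_fa_map`.
#' @export
signal_map <- function(exc_fa_map, exc_phase_map, cfg) {
  stopifnot(inherits(cfg, "epg_config"))
  if (!identical(dim(exc_fa_map), dim(exc_phase_map)) ||
      length(exc_fa_map) != length(exc_phase_map))
    stop("flip-angle and phase maps must have identical shape")
  e <- .epg_batch(as.vector(exc_fa_map), as.vector(exc_phase_map), cfg)
  out <- Mod(e[, cfg$target_echo])
  if (!is.null(dim(exc_fa_map))) dim(out) <- dim(exc_fa_map)
  out
}
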