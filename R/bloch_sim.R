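#' Magnetization state
#'
#' Unit-magnitude magnetization vector (M0 = 1; no relaxation is applied
#' during excitation).
#'
#' @param mx,my,mz Cartesian components.
#' @return Object of class `magnetization_state`.
#' @export
magnetization_state <- function(mx, my, mz) {
  structure(list(mx = mx, my = my, mz = mz), class = "magnetization_state")
}

# batch kernel front-ends -----------------------------------------------

# B1: complex Nsim x Nt (Hz), Om: Nsim x Nt (Hz) -> Nsim x 3 magnetization
.bloch_batch <- function(B1, Om, dt) {
  .bloch_run(Re(B1), Im(B1), Om, dt)
}

.bloch_batch_vjp <- function(B1, Om, dt, Mbar) {
  .bloch_run_vjp(Re(B1), Im(B1), Om, dt, Mbar)
}

# per-voxel transverse drive (Hz, complex, length Nt): b1(t) = sum_c s_c V_c(t)
.voxel_b1 <- function(pulse, sens_row) {
  as.vector(t(pulse$rf) %*% as.complex(sens_row))
}

# longitudinal offset trace (Hz, length Nt)
.voxel_omega <- function(pulse, db0_hz, pos_mm, f_offset_hz) {
  db0_hz + f_offset_hz +
    GAMMA_BAR_HZ_PER_MTM_MM * as.vector(pos_mm %*% pulse$grad)
}

#' Hard-pulse Bloch simulation of one voxel
#'
#' Starting from equilibrium (0, 0, 1), applies for every time sample the
#' exact axis-angle rotation generated by the transverse drive
#' `b1[n] = sum_c s_c * V_c[n]` (Hz, complex) and the longitudinal offset
#' `omega[n] = db0 + f_offset + gamma_bar * grad[, n] . pos` (Hz). A
#' positive offset precesses the transverse magnetization clockwise in the
#' rotating frame (free-precession phase `-2*pi*f*t`).
#'
#' @param pulse A [pulse_waveforms()] object.
#' @param sens_row Complex channel sensitivities of the voxel (Hz/V),
#'   length `n_channels`.
#' @param db0_hz Static off-resonance of the voxel (Hz).
#' @param pos_mm Voxel position (mm), length 3.
#' @param f_offset_hz Additional injected frequency offset (Hz).
#' @return A [magnetization_state()].
#' @export
simulate_voxel <- function(pulse, sens_row, db0_hz = 0,
                           pos_mm = c(0, 0, 0), f_offset_hz = 0) {
  stopifnot(inherits(pulse, "pulse_waveforms"))
  if (length(sens_row) != pulse$n_channels)
    stop("sens_row must have one entry per transmit channel")
  b1 <- .voxel_b1(pulse, sens_row)
  om <- .voxel_omega(pulse, db0_hz, pos_mm, f_offset_hz)
  m <- .bloch_batch(matrix(b1, 1), matrix(om, 1), pulse$dt)
  magnetization_state(m[1, 1], m[1, 2], m[1, 3])
}

#' Flip angle and transverse phase of a magnetization state
#'
#' Flip angle is `atan2(|Mxy|, Mz)` in degrees (robust beyond 90 degrees);
#' phase is `arg(Mx + i My)` in radians, reported as 0 when `|Mxy|` is
#' numerically zero.
#'
#' @param state A [magnetization_state()], or a matrix with columns
#'   (mx, my, mz) for vectorized use.
#' @return List with `fa_deg` and `phase_rad` (vectors for matrix input).
#' @export
flip_angle_and_phase <- function(state) {
  if (inherits(state, "magnetization_state"))
    state <- cbind(state$mx, state$my, state$mz)
  p <- sqrt(state[, 1]^2 + state[, 2]^2)
  fa <- atan2(p, state[, 3]) * 180 / pi
  ph <- ifelse(p < 1e-12, 0, atan2(state[, 2], state[, 1]))
  list(fa_deg = as.vector(fa), phase_rad = as.vector(ph))
}

#' Spectral excitation response of a voxel
#'
#' Simulates [simulate_voxel()] across a set of frequency offsets and
#' collects flip angle and phase per frequency.
#'
#' @inheritParams simulate_voxel
#' @param freqs Frequency offsets in Hz (non-empty).
#' @return Object of class `spectral_response` with `freqs`, `fa_deg`,
#'   `phase_rad`.
#' @export
spectral_response <- function(pulse, sens_row, db0_hz = 0,
                              pos_mm = c(0, 0, 0), freqs) {
  stopifnot(inherits(pulse, "pulse_waveforms"), length(freqs) >= 1)
  b1 <- .voxel_b1(pulse, sens_row)
  nf <- length(freqs)
  B1 <- matrix(b1, nf, pulse$n_samples, byrow = TRUE)
  om0 <- .voxel_omega(pulse, db0_hz, pos_mm, 0)
  Om <- matrix(om0, nf, pulse$n_samples, byrow = TRUE) + freqs
  m <- .bloch_batch(B1, Om, pulse$dt)
  fp <- flip_angle_and_phase(m)
  structure(list(freqs = freqs, fa_deg = fp$fa_deg,
                 phase_rad = fp$phase_rad),
            class = "spectral_response")
}

#' Full width at half maximum of a spectral flip-angle response
#'
#' Linearly interpolates the half-maximum crossings on both sides of the
#' response peak.
#'
#' @param resp A [spectral_response()] (or list with `freqs`, `fa_deg`).
#' @return FWHM in Hz (NA when no crossing brackets the peak).
#' @export
spectral_fwhm <- function(resp) {
  f <- resp$freqs; y <- resp$fa_deg
  o <- order(f); f <- f[o]; y <- y[o]
  ip <- which.max(y)
  half <- y[ip] / 2
  cross <- function(idx_range) {
    yy <- y[idx_range]; ff <- f[idx_range]
    s <- which(diff(yy >= half) != 0)
    if (!length(s)) return(NA_real_)
    i <- s[length(s)]
    ff[i] + (half - yy[i]) * (ff[i + 1] - ff[i]) / (yy[i + 1] - yy[i])
  }
  left <- cross(seq_len(ip))
  yr <- rev(y[ip:length(y)]); fr <- rev(f[ip:length(f)])
  s <- which(diff(yr >= half) != 0)
  right <- if (!length(s)) NA_real_ else {
    i <- s[length(s)]
    fr[i] + (half - yr[i]) * (fr[i + 1] - fr[i]) / (yr[i + 1] - yr[i])
  }
  right - left
}

#' Slice-profile evaluation configuration
#'
#' @param n_spins Number of spins arranged along the profile segment.
#' @param length_mm Segment length in mm.
#' @param g_sel_mtm Constant selection gradient amplitude (mT/m).
#' @param axis Selection axis (1..3).
#' @return Object of class `profile_config`.
#' @export
profile_config <- function(n_spins = 3000L, length_mm = 6,
                           g_sel_mtm = 51.7, axis = 3L) {
  if (n_spins < 2) stop("n_spins must be at least 2")
  structure(list(n_spins = as.integer(n_spins), length_mm = length_mm,
                 g_sel_mtm = g_sel_mtm, axis = as.integer(axis)),
            class = "profile_config")
}

#' Simulated slice profile through one voxel
#'
#' Places `n_spins` equidistant spins along a segment of `length_mm`
#' centred on the voxel, maps each spin position to a frequency offset via
#' the constant selection gradient (`f = gamma_bar * G_sel * x`), linearly
#' interpolates the channel sensitivities and off-resonance along the
#' segment when two end values are supplied, and simulates every spin. The
#' pulse's own gradient waveforms also act on the spin positions.
#'
#' @param pulse A [pulse_waveforms()] object.
#' @param sens Either a length-`n_channels` complex vector (constant along
#'   the segment) or a 2 x `n_channels` matrix of end values that are
#'   linearly interpolated per spin.
#' @param db0_hz Scalar or length-2 off-resonance (Hz), interpolated like
#'   `sens`.
#' @param cfg A [profile_config()].
#' @param center_mm Slice-centre position along the selection axis (mm).
#' @return List of class `slice_profile` with `x_mm`, `mxy` (complex),
#'   `mz`, `spacing_mm`.
#' @export
slice_profile <- function(pulse, sens, db0_hz = 0, cfg = profile_config(),
                          center_mm = 0) {
  stopifnot(inherits(pulse, "pulse_waveforms"),
            inherits(cfg, "profile_config"))
  ns <- cfg$n_spins
  x <- seq(-cfg$length_mm / 2, cfg$length_mm / 2, length.out = ns)
  u <- (x - x[1]) / (x[ns] - x[1])
  if (is.matrix(sens)) {
    S <- outer(1 - u, as.complex(sens[1, ])) + outer(u, as.complex(sens[2, ]))
  } else {
    S <- matrix(as.complex(sens), ns, pulse$n_channels, byrow = TRUE)
  }
  db0 <- if (length(db0_hz) == 2) (1 - u) * db0_hz[1] + u * db0_hz[2]
         else rep(db0_hz, ns)
  B1 <- S %*% pulse$rf
  pos <- matrix(0, ns, 3)
  pos[, cfg$axis] <- center_mm + x
  f_off <- GAMMA_BAR_HZ_PER_MTM_MM * cfg$g_sel_mtm * x
  Om <- (db0 + f_off) +
    GAMMA_BAR_HZ_PER_MTM_MM * pos %*% pulse$grad
  m <- .bloch_batch(B1, Om, pulse$dt)
  structure(list(x_mm = x, mxy = complex(real = m[, 1], imaginary = m[, 2]),
                 mz = m[, 3], spacing_mm = x[2] - x[1]),
            class = "slice_profile")
}

#' Phase-sensitive slice integral
#'
#' Magnitude of the complex sum of the transverse magnetization across the
#' profile, scaled by the spin spacing. Intra-slice dephasing therefore
#' reduces the value, making it a signal proxy that penalizes phase
#' variation along the slice.
#'
#' @param profile A [slice_profile()] object or complex vector of `mxy`.
#' @param spin_spacing Spacing between spins (mm); taken from the profile
#'   object when omitted.
#' @return Scalar slice integral (mm, with M0 = 1).
#' @export
slice_integral <- function(profile, spin_spacing = NULL) {
  if (inherits(profile, "slice_profile")) {
    spin_spacing <- spin_spacing %||% profile$spacing_mm
    profile <- profile$mxy
  }
  if (length(profile) < 2) stop("need at least 2 spins")
  if (is.null(spin_spacing)) stop("spin_spacing required for raw vectors")
  Mod(sum(profile)) * spin_spacing
}
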