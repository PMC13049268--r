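#' Multi-channel RF + gradient waveforms
#'
#' Container for a parallel-transmit pulse: complex RF voltage per channel
#' and per time sample, plus three-axis gradient waveforms on the same
#' uniform time grid.
#'
#' @param rf Complex matrix, channels x time samples (volts).
#' @param grad Numeric matrix, 3 x time samples (mT/m).
#' @param dt Sample duration in seconds.
#' @return An object of class `pulse_waveforms` with fields `rf`, `grad`,
#'   `dt`, `n_channels`, `n_samples` and `duration` (= `n_samples * dt`).
#' @export
pulse_waveforms <- function(rf, grad, dt) {
  if (!is.matrix(rf)) rf <- matrix(rf, nrow = 1)
  rf <- matrix(as.complex(rf), nrow = nrow(rf))
  if (!is.matrix(grad)) grad <- matrix(grad, nrow = 3)
  storage.mode(grad) <- "double"
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (nrow(grad) != 3) stop("grad must have 3 rows (one per axis)")
  if (ncol(grad) != ncol(rf))
    stop("rf and grad must share the same number of time samples")
  if (ncol(rf) < 2) stop("a pulse needs at least 2 time samples")
  if (!all(is.finite(Re(rf))) || !all(is.finite(Im(rf))) ||
      !all(is.finite(grad)))
    stop("waveform samples must be finite")
  structure(
    list(rf = rf, grad = grad, dt = dt,
         n_channels = nrow(rf), n_samples = ncol(rf),
         duration = ncol(rf) * dt),
    class = "pulse_waveforms")
}

#' @export
print.pulse_waveforms <- function(x, ...) {
  cat(sprintf(
    "<pulse_waveforms> %d channels, %d samples, dt = %.3g us, T = %.3g ms\n",
    x$n_channels, x$n_samples, x$dt * 1e6, x$duration * 1e3))
  cat(sprintf("  peak |RF| %.3g V, peak |G| %.3g mT/m\n",
              max(Mod(x$rf)), max(abs(x$grad))))
  invisible(x)
}

# normalized sinc: sin(pi x)/(pi x)
.sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# midpoint sample times relative to the pulse centre; exactly mirror-symmetric
.centered_times <- function(n, dt) (seq_len(n) - (n + 1) / 2) * dt

#' Construct a circularly-polarized (CP) apodized-sinc reference pulse
#'
#' Builds the conventional slice-selective starting pulse: a Hann-apodized
#' sinc envelope, identical on every channel up to a per-channel CP phase
#' increment. The amplitude is calibrated so that the CP channel combination
#' produces the requested on-resonance small-tip flip angle at a reference
#' voxel whose combined sensitivity is `n_channels * ref_sens_hz_per_v`
#' (i.e. all channels add coherently with magnitude `ref_sens_hz_per_v`
#' each, the package's volts-to-field convention).
#'
#' @param fa_deg Target on-resonance flip angle in degrees.
#' @param duration Pulse duration in seconds.
#' @param tbw Time-bandwidth product (>= 2); the small-tip bandwidth is
#'   `tbw / duration` Hz.
#' @param n_channels Number of transmit channels.
#' @param dt Sample duration in seconds.
#' @param cp_phase_increment Per-channel drive phase increment (radians).
#'   The default 0 matches sensitivity maps that are phase-referenced to the
#'   CP mode (the azimuthal coil phase is already folded into the maps, as
#'   [generate_subject()] does); use `2*pi/n_channels` for raw loop maps.
#' @param ref_sens_hz_per_v Per-channel reference transmit sensitivity
#'   (Hz/V) used for the flip-angle calibration.
#' @param sel_grad_mtm Optional constant selection gradient (mT/m).
#' @param sel_axis Axis (1..3) carrying the selection gradient.
#' @return A [pulse_waveforms()] object, time-symmetric by construction.
#' @export
make_cp_sinc <- function(fa_deg, duration, tbw, n_channels = 8L,
                         dt = 1e-5, cp_phase_increment = 0,
                         ref_sens_hz_per_v = 11.75,
                         sel_grad_mtm = 0, sel_axis = 3L) {
  if (fa_deg <= 0) stop("fa_deg must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (tbw < 2) stop("tbw must be at least 2")
  nt <- max(2L, as.integer(round(duration / dt)))
  tau <- .centered_times(nt, dt)
  env <- (0.5 + 0.5 * cos(2 * pi * tau / duration)) * .sinc(tbw * tau / duration)
  # calibrate: 2*pi * sum(b1) * dt = fa_rad with b1 = Nc * ref_sens * V(t)
  fa_cycles <- fa_deg / 360
  amp <- fa_cycles / (n_channels * ref_sens_hz_per_v * sum(env) * dt)
  phases <- exp(1i * cp_phase_increment * (seq_len(n_channels) - 1))
  rf <- outer(phases, amp * env)
  grad <- matrix(0, 3, nt)
  if (sel_grad_mtm != 0) grad[sel_axis, ] <- sel_grad_mtm
  pulse_waveforms(rf, grad, dt)
}

# piecewise-linear interpolation with linear extrapolation from the end
# segments (exact for affine-in-time waveforms)
.interp_extrap <- function(x, y, xout) {
  n <- length(x)
  yi <- approx(x, y, xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    yi[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    yi[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  yi
}

#' Resample a pulse onto a new time grid
#'
#' Linearly interpolates real and imaginary RF parts and the gradient
#' waveforms onto a grid with sample duration `dt_new`, preserving the total
#' duration to within one new sample. Samples represent interval midpoints;
#' the end segments are extrapolated linearly so affine waveforms are
#' reproduced exactly.
#'
#' @param pulse A [pulse_waveforms()] object.
#' @param dt_new New sample duration in seconds.
#' @return A [pulse_waveforms()] object on the new grid.
#' @export
resample_linear <- function(pulse, dt_new) {
  stopifnot(inherits(pulse, "pulse_waveforms"))
  if (dt_new <= 0) stop("dt_new must be positive")
  if (isTRUE(all.equal(dt_new, pulse$dt))) return(pulse)
  nt_new <- max(2L, as.integer(round(pulse$duration / dt_new)))
  t_old <- .centered_times(pulse$n_samples, pulse$dt)
  t_new <- .centered_times(nt_new, dt_new)
  rf <- matrix(0i, pulse$n_channels, nt_new)
  for (c in seq_len(pulse$n_channels)) {
    rf[c, ] <- .interp_extrap(t_old, Re(pulse$rf[c, ]), t_new) +
      1i * .interp_extrap(t_old, Im(pulse$rf[c, ]), t_new)
  }
  grad <- t(vapply(1:3, function(a)
    .interp_extrap(t_old, pulse$grad[a, ], t_new), numeric(nt_new)))
  pulse_waveforms(rf, grad, dt_new)
}

#' Deposited RF energy of a pulse
#'
#' `E = sum_c sum_n |V_c[n]|^2 * dt / Z`, reported in millijoules.
#'
#' @param pulse A [pulse_waveforms()] object.
#' @param impedance_ohm Load impedance (default 50 Ohm).
#' @return Energy in mJ.
#' @export
pulse_energy <- function(pulse, impedance_ohm = 50) {
  stopifnot(inherits(pulse, "pulse_waveforms"))
  if (impedance_ohm <= 0) stop("impedance must be positive")
  1e3 * sum(Mod(pulse$rf)^2) * pulse$dt / impedance_ohm
}

#' Scanner hardware limits
#'
#' Default values are the constraint set used throughout: 70 mT/m peak
#' gradient, 200 T/m/s slew rate, 190 V peak channel voltage, 8 W total and
#' 1 W per-channel time-average RF power.
#'
#' @param g_max Peak gradient amplitude (mT/m).
#' @param slew_max Peak gradient slew rate (T/m/s).
#' @param v_peak Peak RF voltage per channel (V).
#' @param p_total Total time-average RF power (W).
#' @param p_channel Per-channel time-average RF power (W).
#' @return An object of class `hardware_limits`.
#' @export
hardware_limits <- function(g_max = 70, slew_max = 200, v_peak = 190,
                            p_total = 8, p_channel = 1) {
  vals <- c(g_max = g_max, slew_max = slew_max, v_peak = v_peak,
            p_total = p_total, p_channel = p_channel)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hardware limits must be strictly positive")
  structure(as.list(vals), class = "hardware_limits")
}

# slew rate trace in T/m/s including the ramps from/to zero at the edges;
# edge ramps are taken over edge_dt (default: the pulse's own dt)
.slew_trace <- function(grad, dt, edge_dt = dt) {
  nt <- ncol(grad)
  inner <- if (nt > 1) abs(grad[, -1, drop = FALSE] -
                           grad[, -nt, drop = FALSE]) / dt else NULL
  edges <- cbind(abs(grad[, 1]) / edge_dt, abs(grad[, nt]) / edge_dt)
  1e-3 * cbind(edges[, 1], inner, edges[, 2]) # mT/m -> T/m
}

#' Check a pulse against hardware limits
#'
#' Measures the peak RF voltage, per-axis peak gradient, peak slew rate
#' (sample-to-sample differences plus the ramps from and to zero at the
#' pulse edges), per-channel and total time-average RF power, and compares
#' each against [hardware_limits()].
#'
#' @param pulse A [pulse_waveforms()] object.
#' @param limits A [hardware_limits()] object.
#' @param impedance_ohm Load impedance for the power checks.
#' @param tol Relative tolerance for the pass decision.
#' @param edge_dt Ramp duration assumed at the pulse edges (s); defaults to
#'   the pulse's own sample duration.
#' @return A `limit_report`: data frame with `limit`, `measured`, `bound`,
#'   `pass`, plus attribute `all_pass`.
#' @export
check_limits <- function(pulse, limits = hardware_limits(),
                         impedance_ohm = 50, tol = 1e-9,
                         edge_dt = pulse$dt) {
  stopifnot(inherits(pulse, "pulse_waveforms"),
            inherits(limits, "hardware_limits"))
  v_meas <- max(Mod(pulse$rf))
  g_meas <- max(abs(pulse$grad))
  s_meas <- max(.slew_trace(pulse$grad, pulse$dt, edge_dt))
  p_ch <- rowSums(Mod(pulse$rf)^2) * pulse$dt / impedance_ohm / pulse$duration
  rep <- data.frame(
    limit = c("v_peak", "g_max", "slew_max", "p_channel", "p_total"),
    measured = c(v_meas, g_meas, s_meas, max(p_ch), sum(p_ch)),
    bound = c(limits$v_peak, limits$g_max, limits$slew_max,
              limits$p_channel, limits$p_total))
  rep$pass <- rep$measured <= rep$bound * (1 + tol)
  structure(rep, all_pass = all(rep$pass), class = c("limit_report",
                                                     "data.frame"))
}

#' @export
print.limit_report <- function(x, ...) {
  cat("<limit_report>", if (attr(x, "all_pass")) "PASS" else "FAIL", "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# number of free time samples of a symmetric pulse (first half + centre)
.n_half <- function(nt) (nt + 1L) %/% 2L

#' Expand symmetric half-parameters into full waveforms
#'
#' The optimizer works on the first half of the time grid (plus the centre
#' sample when the sample count is odd); this expands such a parameter
#' vector into time-symmetric waveforms with `rf[, n] == rf[, Nt + 1 - n]`
#' and likewise for the gradients. Layout of `half_parameters`:
#' `[Re RF (Nc x Nh), Im RF (Nc x Nh), grad (3 x Nh)]`, column-major.
#'
#' @param half_parameters Numeric vector of length `(2*n_channels + 3) * Nh`
#'   with `Nh = ceiling(n_samples / 2)`.
#' @param n_channels,n_samples Shape of the full pulse.
#' @param dt Sample duration (s).
#' @return A [pulse_waveforms()] object.
#' @seealso [half_parameters()] for the inverse extraction.
#' @export
symmetrize <- function(half_parameters, n_channels, n_samples, dt) {
  nh <- .n_half(n_samples)
  need <- (2L * n_channels + 3L) * nh
  if (length(half_parameters) != need)
    stop(sprintf("half_parameters has length %d, expected %d",
                 length(half_parameters), need))
  re <- matrix(half_parameters[seq_len(n_channels * nh)], n_channels, nh)
  im <- matrix(half_parameters[n_channels * nh + seq_len(n_channels * nh)],
               n_channels, nh)
  gh <- matrix(half_parameters[2L * n_channels * nh + seq_len(3L * nh)], 3, nh)
  mirror <- function(m) {
    tail <- m[, rev(seq_len(n_samples - nh)), drop = FALSE]
    cbind(m, tail)
  }
  pulse_waveforms(mirror(re + 1i * im), mirror(gh), dt)
}

#' Extract the symmetric half-parameter vector of a pulse
#'
#' @param pulse A time-symmetric [pulse_waveforms()] object.
#' @return Numeric vector accepted by [symmetrize()].
#' @export
half_parameters <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_waveforms"))
  nh <- .n_half(pulse$n_samples)
  c(Re(pulse$rf[, seq_len(nh)]), Im(pulse$rf[, seq_len(nh)]),
    pulse$grad[, seq_len(nh)])
}

#' Write / read a pulse archive
#'
#' Structured JSON text container with named arrays `rf_real`, `rf_imag`
#' (channels x samples), `grad` (3 x samples), the scalar `dt_s` and a free
#' metadata list. Round-trips are lossless at double precision.
#'
#' @param pulse A [pulse_waveforms()] object.
#' @param path File path.
#' @param meta Optional metadata list (design config hash, seed, ...).
#' @return `write_pulse` returns `path` invisibly; `read_pulse` returns a
#'   [pulse_waveforms()] object with the metadata in `attr(, "meta")`.
#' @export
write_pulse <- function(pulse, path, meta = list()) {
  stopifnot(inherits(pulse, "pulse_waveforms"))
  obj <- list(format = "ptxgrape-pulse-1",
              dt_s = pulse$dt,
              n_channels = pulse$n_channels,
              n_samples = pulse$n_samples,
              rf_real = Re(pulse$rf), rf_imag = Im(pulse$rf),
              grad = pulse$grad, meta = meta)
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              pretty = FALSE), path)
  invisible(path)
}

#' @rdname write_pulse
#' @export
read_pulse <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$rf_real) || is.null(obj$grad) || is.null(obj$dt_s))
    stop("not a pulse archive: ", path)
  rf <- matrix(obj$rf_real, obj$n_channels) +
    1i * matrix(obj$rf_imag, obj$n_channels)
  p <- pulse_waveforms(rf, matrix(obj$grad, 3), obj$dt_s)
  attr(p, "meta") <- obj$meta
  p
}
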