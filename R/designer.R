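#' Design configuration
#'
#' Bundles the target, weighting, hardware limits and optimizer settings
#' of a pulse design run.
#'
#' @param target A [target_spec()].
#' @param weighting A [weighting_config()].
#' @param limits A [hardware_limits()].
#' @param duration_s Pulse duration (s).
#' @param dt_coarse_s Optimization sample duration (s).
#' @param dt_fine_s Final (playout) sample duration (s); the optimized
#'   pulse is linearly interpolated onto this grid.
#' @param max_iter Inner quasi-Newton iteration cap of each of the four
#'   penalty continuation rounds.
#' @param tol Convergence tolerance passed to the inner solver.
#' @param seed Seed for the per-voxel frequency draws (drawn once per
#'   design and held fixed, keeping the objective deterministic).
#' @param freq_dist Frequency-offset distribution descriptor (see
#'   [sample_frequencies()]).
#' @param n_freq_per_voxel Offsets per voxel.
#' @param init_tbw Time-bandwidth product of the CP-sinc initialization;
#'   `NULL` uses `bandwidth_hz * duration_s` so the starting pulse already
#'   has the target bandwidth.
#' @param ref_sens_hz_per_v Volts-to-field calibration (see
#'   [make_cp_sinc()]).
#' @param impedance_ohm Impedance for energy/power accounting.
#' @param sel_axis Slice/slab selection axis (1..3).
#' @param roi_decay_mm ROI weight decay for slice-specific designs.
#' @return Object of class `design_config`.
#' @export
design_config <- function(target = target_spec(90, 2500),
                          weighting = weighting_config(lambda_ph = 3,
                                                       lambda_b0 = 0.01),
                          limits = hardware_limits(),
                          duration_s = 3e-3,
                          dt_coarse_s = 3e-5,
                          dt_fine_s = 1e-5,
                          max_iter = 300L,
                          tol = 1e-9,
                          seed = 1L,
                          freq_dist = list(name = "uniform",
                                           min_hz = -6250, max_hz = 6250),
                          n_freq_per_voxel = 3L,
                          init_tbw = NULL,
                          ref_sens_hz_per_v = 11.75,
                          impedance_ohm = 50,
                          sel_axis = 3L,
                          roi_decay_mm = 10) {
  if (duration_s <= 0 || dt_coarse_s <= 0 || dt_fine_s <= 0)
    stop("duration_s, dt_coarse_s and dt_fine_s must be positive")
  if (dt_coarse_s < dt_fine_s) stop("dt_coarse_s must be >= dt_fine_s")
  structure(list(target = target, weighting = weighting, limits = limits,
                 duration_s = duration_s, dt_coarse_s = dt_coarse_s,
                 dt_fine_s = dt_fine_s, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed), freq_dist = freq_dist,
                 n_freq_per_voxel = as.integer(n_freq_per_voxel),
                 init_tbw = init_tbw,
                 ref_sens_hz_per_v = ref_sens_hz_per_v,
                 impedance_ohm = impedance_ohm,
                 sel_axis = as.integer(sel_axis),
                 roi_decay_mm = roi_decay_mm),
            class = "design_config")
}

# fold a full-waveform gradient onto the symmetric half-parameters
.fold_half <- function(G, nt) {
  nh <- (nt + 1L) %/% 2L
  H <- G[, seq_len(nh), drop = FALSE]
  ntail <- nt - nh
  if (ntail > 0)
    H[, seq_len(ntail)] <- H[, seq_len(ntail)] +
      G[, nt:(nh + 1L), drop = FALSE]
  H
}

# smooth quartic-hinge penalty for the hardware limits; gradients w.r.t.
# the full rf (complex convention: d/dRe + 1i * d/dIm) and grad arrays.
# eta < 1 leaves margin so the exact check passes after convergence.
.penalty_eval <- function(rf, grad, dt, limits, impedance_ohm, edge_dt,
                          eta = 0.98) {
  nt <- ncol(rf)
  P <- 0
  Grf <- matrix(0i, nrow(rf), nt)
  Gg <- matrix(0, 3, nt)

  v2 <- Re(rf * Conj(rf))
  vl2 <- (eta * limits$v_peak)^2
  hv <- pmax(0, v2 - vl2)
  if (any(hv > 0)) {
    P <- P + sum(hv^2) / limits$v_peak^4
    Grf <- Grf + (4 * hv / limits$v_peak^4) * rf
  }

  gl2 <- (eta * limits$g_max)^2
  hg <- pmax(0, grad^2 - gl2)
  if (any(hg > 0)) {
    P <- P + sum(hg^2) / limits$g_max^4
    Gg <- Gg + 4 * hg * grad / limits$g_max^4
  }

  # slew in T/m/s; interior differences plus edge ramps over edge_dt
  sl_in <- if (nt > 1) 1e-3 * (grad[, -1, drop = FALSE] -
                               grad[, -nt, drop = FALSE]) / dt else NULL
  sl_e1 <- 1e-3 * grad[, 1] / edge_dt
  sl_e2 <- 1e-3 * grad[, nt] / edge_dt
  sl2 <- (eta * limits$slew_max)^2
  s4 <- limits$slew_max^4
  if (!is.null(sl_in)) {
    h <- pmax(0, sl_in^2 - sl2)
    if (any(h > 0)) {
      P <- P + sum(h^2) / s4
      d <- 4 * h * sl_in * 1e-3 / dt / s4
      Gg[, -1] <- Gg[, -1, drop = FALSE] + d
      Gg[, -nt] <- Gg[, -nt, drop = FALSE] - d
    }
  }
  for (edge in list(list(i = 1L, s = sl_e1), list(i = nt, s = sl_e2))) {
    h <- pmax(0, edge$s^2 - sl2)
    if (any(h > 0)) {
      P <- P + sum(h^2) / s4
      Gg[, edge$i] <- Gg[, edge$i] + 4 * h * edge$s * 1e-3 / edge_dt / s4
    }
  }

  # time-average power per channel and total (W)
  pc <- rowSums(v2) / (impedance_ohm * nt)
  hp <- pmax(0, pc - eta * limits$p_channel)
  if (any(hp > 0)) {
    P <- P + sum(hp^2) / limits$p_channel^2
    Grf <- Grf + (2 * hp / limits$p_channel^2) *
      (2 / (impedance_ohm * nt)) * rf
  }
  ht <- max(0, sum(pc) - eta * limits$p_total)
  if (ht > 0) {
    P <- P + ht^2 / limits$p_total^2
    Grf <- Grf + (2 * ht / limits$p_total^2) *
      (2 / (impedance_ohm * nt)) * rf
  }
  list(value = P, grad_rf = Grf, grad_grad = Gg)
}

# scale RF/gradients down to exact feasibility (all limits are positively
# homogeneous in the respective waveform)
.project_feasible <- function(pulse, limits, impedance_ohm, edge_dt,
                              margin = 1) {
  v <- max(Mod(pulse$rf))
  pc <- rowSums(Mod(pulse$rf)^2) * pulse$dt / impedance_ohm / pulse$duration
  s_rf <- min(1, margin * limits$v_peak / max(v, 1e-300),
              sqrt(margin * limits$p_channel / max(max(pc), 1e-300)),
              sqrt(margin * limits$p_total / max(sum(pc), 1e-300)))
  g <- max(abs(pulse$grad))
  sl <- max(.slew_trace(pulse$grad, pulse$dt, edge_dt))
  s_g <- min(1, margin * limits$g_max / max(g, 1e-300),
             margin * limits$slew_max / max(sl, 1e-300))
  if (s_rf < 1 || s_g < 1)
    pulse <- pulse_waveforms(pulse$rf * s_rf, pulse$grad * s_g, pulse$dt)
  pulse
}

# flip angles at f = 0 for all masked voxels of a subject-voxel list
.fa_at_center <- function(rf, grad, dt, sub) {
  B1 <- sub$sens %*% rf
  Om <- GAMMA_BAR_HZ_PER_MTM_MM * (sub$pos %*% grad) + sub$db0
  m <- .bloch_batch(B1, Om, dt)
  flip_angle_and_phase(m)$fa_deg
}

#' Flip-angle normalized root-mean-square error
#'
#' `100 * sqrt(mean((FA - FAT)^2)) / FAT`, in percent.
#'
#' @param fa_values Simulated flip angles (deg), non-empty.
#' @param fa_target Target flip angle (deg).
#' @return NRMSE in percent.
#' @export
fa_nrmse <- function(fa_values, fa_target) {
  if (!length(fa_values)) stop("fa_values must be non-empty")
  100 * sqrt(mean((fa_values - fa_target)^2)) / fa_target
}

#' Constrained universal pulse design
#'
#' Minimizes the cohort cost ([pulse_cost()]) over the symmetric
#' half-parameters of the RF and gradient waveforms on the coarse time
#' grid, subject to the hardware limits. Constraints are enforced through
#' an escalating smooth quadratic-penalty scheme around a quasi-Newton
#' (L-BFGS-B) inner solver driven by analytic adjoint-state gradients;
#' after each penalty round the iterate is checked against the exact
#' per-sample limits and the best feasible iterate is retained. The final
#' pulse is projected to exact feasibility, resampled to the fine grid and
#' re-verified. Deterministic given `(config, cohort)`.
#'
#' @param config A [design_config()].
#' @param cohort List of `subject_fieldmap` objects (or masked-voxel
#'   lists).
#' @param roi Optional per-subject ROI weight vectors.
#' @param init Optional initialization: a [pulse_waveforms()] object
#'   (resampled to the coarse grid as needed). Default: CP sinc at the
#'   target flip angle and bandwidth.
#' @param verbose Print per-round progress.
#' @return Object of class `design_result` with elements `pulse` (fine
#'   grid), `pulse_coarse`, `cost` (final [pulse_cost()] breakdown),
#'   `cost_trace`, `limit_report`, `metrics` (per-subject passband FA
#'   NRMSE for the initialization and the result, energy), `converged`.
#' @export
design_pulse <- function(config, cohort, roi = NULL, init = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "design_config"))
  if (!length(cohort)) stop("cohort must be non-empty")
  subjects <- lapply(cohort, function(s)
    if (inherits(s, "subject_fieldmap")) fieldmap_voxels(s) else s)
  nc <- ncol(subjects[[1]]$sens)
  spec <- config$target
  cfg <- config$weighting
  dtc <- config$dt_coarse_s

  samples <- lapply(seq_along(subjects), function(s)
    sample_frequencies(nrow(subjects[[s]]$sens), config$freq_dist,
                       config$n_freq_per_voxel, cfg$delta_f_hz,
                       seed = config$seed + 104729L * s))

  if (is.null(init)) {
    tbw <- config$init_tbw %||% (spec$bandwidth_hz * config$duration_s)
    init <- make_cp_sinc(spec$fa_deg, config$duration_s, tbw, nc,
                         dt = dtc,
                         ref_sens_hz_per_v = config$ref_sens_hz_per_v)
  } else if (!isTRUE(all.equal(init$dt, dtc))) {
    init <- resample_linear(init, dtc)
  }
  rep0 <- check_limits(init, config$limits, config$impedance_ohm,
                       edge_dt = config$dt_fine_s)
  if (!attr(rep0, "all_pass")) {
    warning("initialization violates hardware limits; projected to feasibility")
    init <- .project_feasible(init, config$limits, config$impedance_ohm,
                              config$dt_fine_s, margin = 0.98)
  }
  nt <- init$n_samples

  eval_xc <- function(x, want_grad) {
    p <- symmetrize(x, nc, nt, dtc)
    .cost_eval(p$rf, p$grad, dtc, subjects, samples, spec, cfg,
               roi = roi, want_grad = want_grad)
  }

  cache <- new.env(parent = emptyenv())
  make_objective <- function(mu) {
    list(
      fn = function(x) {
        cres <- eval_xc(x, TRUE)
        p <- symmetrize(x, nc, nt, dtc)
        pen <- .penalty_eval(p$rf, p$grad, dtc, config$limits,
                             config$impedance_ohm, config$dt_fine_s)
        g_rf <- .fold_half(cres$grad_rf + mu * pen$grad_rf, nt)
        g_gr <- .fold_half(cres$grad_grad + mu * pen$grad_grad, nt)
        cache$x <- x
        cache$grad <- c(Re(g_rf), Im(g_rf), g_gr)
        cache$cost <- cres$total
        cres$total + mu * pen$value
      },
      gr = function(x) {
        if (!identical(x, cache$x)) {
          cres <- eval_xc(x, TRUE)
          p <- symmetrize(x, nc, nt, dtc)
          pen <- .penalty_eval(p$rf, p$grad, dtc, config$limits,
                               config$impedance_ohm, config$dt_fine_s)
          g_rf <- .fold_half(cres$grad_rf + mu * pen$grad_rf, nt)
          g_gr <- .fold_half(cres$grad_grad + mu * pen$grad_grad, nt)
          cache$x <- x
          cache$grad <- c(Re(g_rf), Im(g_rf), g_gr)
          cache$cost <- cres$total
        }
        cache$grad
      })
  }

  x <- half_parameters(init)
  cost_init <- eval_xc(x, FALSE)$total
  best_x <- x
  best_cost <- cost_init
  trace <- c(init = cost_init)
  mus <- c(10, 3e2, 9e3, 2.7e5)
  inner <- max(10L, config$max_iter)
  converged <- TRUE
  for (mu in mus) {
    obj <- make_objective(mu)
    opt <- optim(x, obj$fn, obj$gr, method = "L-BFGS-B",
                 control = list(maxit = inner, factr = config$tol / 1e-15))
    x <- opt$par
    if (opt$convergence > 1) converged <- FALSE
    p_it <- .project_feasible(symmetrize(x, nc, nt, dtc), config$limits,
                              config$impedance_ohm, config$dt_fine_s)
    c_it <- .cost_eval(p_it$rf, p_it$grad, dtc, subjects, samples, spec,
                       cfg, roi = roi, want_grad = FALSE)$total
    trace <- c(trace, c_it)
    if (c_it <= best_cost) {
      best_cost <- c_it
      best_x <- half_parameters(p_it)
    }
    if (verbose)
      message(sprintf("mu = %-8.3g cost = %.6g (best %.6g)", mu, c_it,
                      best_cost))
  }

  pulse_coarse <- .project_feasible(symmetrize(best_x, nc, nt, dtc),
                                    config$limits, config$impedance_ohm,
                                    config$dt_fine_s)
  pulse_fine <- .project_feasible(resample_linear(pulse_coarse,
                                                  config$dt_fine_s),
                                  config$limits, config$impedance_ohm,
                                  config$dt_fine_s)
  report <- check_limits(pulse_fine, config$limits, config$impedance_ohm,
                         edge_dt = config$dt_fine_s)
  cost_final <- .cost_eval(pulse_coarse$rf, pulse_coarse$grad, dtc,
                           subjects, samples, spec, cfg, roi = roi,
                           want_grad = FALSE)

  nrmse_init <- vapply(subjects, function(sub)
    fa_nrmse(.fa_at_center(init$rf, init$grad, dtc, sub), spec$fa_deg),
    numeric(1))
  nrmse_final <- vapply(subjects, function(sub)
    fa_nrmse(.fa_at_center(pulse_coarse$rf, pulse_coarse$grad, dtc, sub),
             spec$fa_deg), numeric(1))

  structure(list(
    pulse = pulse_fine, pulse_coarse = pulse_coarse,
    cost = cost_final, cost_trace = trace,
    limit_report = report,
    metrics = list(
      nrmse_init_pct = nrmse_init, nrmse_pct = nrmse_final,
      energy_mj = pulse_energy(pulse_fine, config$impedance_ohm)),
    samples = samples, init = init, config = config,
    converged = converged), class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf(
    "<design_result> cost %.5g (init %.5g), FA NRMSE %.2f%% (init %.2f%%), E = %.1f mJ, limits %s\n",
    x$cost$total, x$cost_trace[1], mean(x$metrics$nrmse_pct),
    mean(x$metrics$nrmse_init_pct), x$metrics$energy_mj,
    if (attr(x$limit_report, "all_pass")) "PASS" else "FAIL"))
  invisible(x)
}

#' Slice-specific (ROI) pulse design
#'
#' Optimizes pulses for individual slice positions: every voxel's cost
#' contribution is weighted by [roi_weight()] of its distance from the
#' slice centre along the selection axis. To halve the computation only
#' the slices at odd list positions (0-based even indices) are optimized;
#' each following slice reuses the preceding result. Every optimization
#' warm-starts from the whole-volume pulse.
#'
#' @param config A [design_config()].
#' @param cohort List of subjects.
#' @param slice_positions Slice centres along the selection axis (mm from
#'   isocenter), non-empty.
#' @param init Whole-volume warm start: a `design_result`, a
#'   [pulse_waveforms()] object, or `NULL` to run [design_pulse()] first.
#' @param verbose Print progress.
#' @return List of `design_result`, one per slice position.
#' @export
design_roi <- function(config, cohort, slice_positions, init = NULL,
                       verbose = FALSE) {
  if (!length(slice_positions)) stop("slice_positions must be non-empty")
  subjects <- lapply(cohort, function(s)
    if (inherits(s, "subject_fieldmap")) fieldmap_voxels(s) else s)
  if (is.null(init)) init <- design_pulse(config, subjects,
                                          verbose = verbose)
  init_pulse <- if (inherits(init, "design_result")) init$pulse_coarse
                else init
  results <- vector("list", length(slice_positions))
  for (k in seq_along(slice_positions)) {
    if (k %% 2 == 0) {
      results[[k]] <- results[[k - 1]]
      next
    }
    z0 <- slice_positions[k]
    roi <- lapply(subjects, function(sub)
      roi_weight(abs(sub$pos[, config$sel_axis] - z0),
                 config$roi_decay_mm))
    results[[k]] <- design_pulse(config, subjects, roi = roi,
                                 init = init_pulse, verbose = verbose)
  }
  results
}

#' Magnitude-least-squares B1+ shim baseline
#'
#' Static pTx baseline: one complex weight per channel, shared temporal
#' waveform. Minimizes `sum_roi (|sum_c w_c s_c(r)| - t)^2` by alternating
#' phase updates and complex least squares, then scales the weights so the
#' mean combined magnitude equals the CP reference combination
#' (`n_channels * ref_sens_hz_per_v`), making them directly usable with
#' the [make_cp_sinc()] amplitude calibration at `fa_target`.
#'
#' @param cohort A `subject_fieldmap`, masked-voxel list, or list of
#'   either; sensitivities of all subjects are pooled.
#' @param roi_mask Optional logical vector (per pooled voxel) restricting
#'   the shim region.
#' @param fa_target Target flip angle (deg), stored as attribute.
#' @param ref_sens_hz_per_v Reference sensitivity of the calibration.
#' @param n_iter Alternating-projection iterations.
#' @return Complex weight vector (length `n_channels`) with attributes
#'   `fa_target` and `objective` (final MLS objective value).
#' @export
b1_shim_baseline <- function(cohort, roi_mask = NULL, fa_target = 90,
                             ref_sens_hz_per_v = 11.75, n_iter = 60L) {
  if (inherits(cohort, "subject_fieldmap") ||
      (is.list(cohort) && !is.null(cohort$sens)))
    cohort <- list(cohort)
  subjects <- lapply(cohort, function(s)
    if (inherits(s, "subject_fieldmap")) fieldmap_voxels(s) else s)
  S <- do.call(rbind, lapply(subjects, `[[`, "sens"))
  if (!is.null(roi_mask)) {
    if (length(roi_mask) != nrow(S))
      stop("roi_mask length must match the pooled voxel count")
    S <- S[roi_mask, , drop = FALSE]
  }
  if (!nrow(S)) stop("shim ROI is empty")
  if (all(Mod(S) == 0)) stop("all-zero sensitivities")
  nc <- ncol(S)
  tmag <- nc * ref_sens_hz_per_v
  w <- rep(1 + 0i, nc)
  SH <- Conj(t(S))
  A <- SH %*% S
  mls_obj <- function(w) sum((Mod(S %*% w) - tmag)^2)
  best <- w
  best_obj <- mls_obj(w)
  for (it in seq_len(n_iter)) {
    z <- S %*% w
    ph <- ifelse(Mod(z) > 0, z / Mod(z), 1 + 0i)
    w <- solve(A, SH %*% (tmag * ph))
    o <- mls_obj(w)
    if (o < best_obj) {
      best <- w
      best_obj <- o
    }
  }
  w <- as.vector(best)
  w <- w * tmag / mean(Mod(S %*% w))
  structure(w, fa_target = fa_target, objective = mls_obj(w))
}

#' Apply static channel weights to a shared-envelope pulse
#'
#' Multiplies each channel's RF waveform by a complex weight (e.g. from
#' [b1_shim_baseline()]); gradients are unchanged.
#'
#' @param pulse A [pulse_waveforms()] object.
#' @param weights Complex vector, one entry per channel.
#' @return A [pulse_waveforms()] object.
#' @export
apply_channel_weights <- function(pulse, weights) {
  stopifnot(inherits(pulse, "pulse_waveforms"),
            length(weights) == pulse$n_channels)
  pulse_waveforms(pulse$rf * as.complex(weights), pulse$grad, pulse$dt)
}
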