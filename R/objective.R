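#' Target spectral excitation profile
#'
#' Rectangular target: the flip angle equals `fa_deg` inside the passband
#' `|f| <= bandwidth_hz / 2` (closed boundary) and zero outside.
#'
#' @param fa_deg Target flip angle FAT in degrees (> 0).
#' @param bandwidth_hz Target bandwidth BWT in Hz (> 0).
#' @return Object of class `target_spec`.
#' @export
target_spec <- function(fa_deg, bandwidth_hz) {
  if (fa_deg <= 0 || bandwidth_hz <= 0)
    stop("fa_deg and bandwidth_hz must be positive")
  structure(list(fa_deg = fa_deg, bandwidth_hz = bandwidth_hz),
            class = "target_spec")
}

#' @rdname target_spec
#' @param f Frequency offset(s) in Hz.
#' @param spec A `target_spec`.
#' @return `target_fa` returns the target flip angle in degrees.
#' @export
target_fa <- function(f, spec) {
  ifelse(abs(f) <= spec$bandwidth_hz / 2, spec$fa_deg, 0)
}

#' Cost-function weighting configuration
#'
#' Houses the balance parameters of the design cost: the phase-term weight
#' `lambda_ph`, the off-resonance voxel weight slope `lambda_b0` (per Hz of
#' |deltaB0|), the phase-pair frequency shift `delta_f_hz`, the shape of
#' the frequency profile weight (raised-cosine transition of total width
#' `transition_frac * BWT` centred on the passband edges, with a stopband
#' plateau), and the flip-angle gate of the phase term (tanh step centred
#' at `wph_center_frac * FAT` with steepness `wph_steepness` per degree,
#' default `10 / FAT` so the step saturates within +-20% of FAT around its
#' centre).
#'
#' @param lambda_ph Phase-consistency term weight (>= 0).
#' @param lambda_b0 Off-resonance weight slope in 1/Hz (>= 0).
#' @param delta_f_hz Frequency shift of the phase pair (Hz, > 0).
#' @param transition_frac Transition-band width as a fraction of BWT.
#' @param stopband_weight Profile-weight plateau deep in the stopband.
#' @param wph_steepness Steepness of the tanh gate (1/deg); `NULL` for the
#'   FAT-dependent default.
#' @param wph_center_frac Centre of the tanh gate as a fraction of FAT.
#' @return Object of class `weighting_config`.
#' @export
weighting_config <- function(lambda_ph = 3, lambda_b0 = 0.02,
                             delta_f_hz = 100, transition_frac = 0.3,
                             stopband_weight = 0.5, wph_steepness = NULL,
                             wph_center_frac = 0.20) {
  if (lambda_ph < 0 || lambda_b0 < 0) stop("lambda weights must be >= 0")
  if (delta_f_hz <= 0) stop("delta_f_hz must be positive")
  if (transition_frac <= 0 || transition_frac >= 1)
    stop("transition_frac must lie in (0, 1)")
  structure(list(lambda_ph = lambda_ph, lambda_b0 = lambda_b0,
                 delta_f_hz = delta_f_hz, transition_frac = transition_frac,
                 stopband_weight = stopband_weight,
                 wph_steepness = wph_steepness,
                 wph_center_frac = wph_center_frac),
            class = "weighting_config")
}

#' Frequency profile weight
#'
#' 1 deep in the passband, decaying smoothly (raised cosine) to exactly 0
#' at the passband edges `+-BWT/2`, then rising to the configured stopband
#' plateau; continuous everywhere. De-weighting the transition band keeps
#' the unavoidable smooth flip-angle roll-off from dominating the
#' quadratic cost.
#'
#' @param f Frequency offset(s), Hz.
#' @param spec A [target_spec()].
#' @param cfg A [weighting_config()].
#' @return Weight(s) >= 0.
#' @export
weight_profile <- function(f, spec, cfg = weighting_config()) {
  half_bw <- spec$bandwidth_hz / 2
  hw <- cfg$transition_frac * spec$bandwidth_hz / 2 # transition half-width
  af <- abs(f)
  w <- numeric(length(af))
  w[af <= half_bw - hw] <- 1
  inner <- af > half_bw - hw & af <= half_bw
  w[inner] <- 0.5 * (1 + cos(pi * (af[inner] - (half_bw - hw)) / hw))
  outer_band <- af > half_bw & af < half_bw + hw
  w[outer_band] <- cfg$stopband_weight *
    0.5 * (1 - cos(pi * (af[outer_band] - half_bw) / hw))
  w[af >= half_bw + hw] <- cfg$stopband_weight
  w
}

#' Per-voxel weighting combining frequency profile and off-resonance
#'
#' `w = wprofile(f) * (1 + lambda_b0 * |deltaB0|)`: voxels with strong
#' static field deviations receive additional weight so the design does
#' not sacrifice them. The absolute value keeps the weight admissible
#' (non-negative) for either off-resonance sign.
#'
#' @param db0_hz Voxel off-resonance (Hz).
#' @inheritParams weight_profile
#' @return Weight(s) >= 0.
#' @export
weight_voxel <- function(db0_hz, f, cfg = weighting_config(), spec) {
  weight_profile(f, spec, cfg) * (1 + cfg$lambda_b0 * abs(db0_hz))
}

.wph_k <- function(spec, cfg) cfg$wph_steepness %||% (10 / spec$fa_deg)

#' Flip-angle gate of the phase-consistency term
#'
#' Smooth differentiable step `0.5 * (1 + tanh(k * (FA - c * FAT)))` with
#' centre fraction `c` (default 20% of FAT): phase errors where hardly any
#' magnetization is excited should not influence the design.
#'
#' @param fa_deg Simulated flip angle(s), degrees.
#' @inheritParams weight_profile
#' @return Weight(s) in \[0, 1\].
#' @export
weight_phase <- function(fa_deg, spec, cfg = weighting_config()) {
  k <- .wph_k(spec, cfg)
  0.5 * (1 + tanh(k * (fa_deg - cfg$wph_center_frac * spec$fa_deg)))
}

#' Draw per-voxel random frequency offsets
#'
#' Every voxel receives its own independent set of `n_per_voxel` offsets
#' (unique sets per voxel avoid coherent spectral oscillations across the
#' volume), each paired with `f + delta_f` for the phase-consistency term.
#' Deterministic under `seed`.
#'
#' @param n_voxels Number of masked voxels.
#' @param dist Distribution descriptor: `list(name = "gaussian",
#'   sigma_hz = ...)` or `list(name = "uniform", min_hz = ..., max_hz =
#'   ...)`.
#' @param n_per_voxel Offsets per voxel (>= 1).
#' @param delta_f_hz Pairing shift (Hz).
#' @param seed Integer seed.
#' @return Object of class `frequency_samples` with matrices `f` and
#'   `f_delta` (`n_per_voxel` x `n_voxels`).
#' @export
sample_frequencies <- function(n_voxels, dist, n_per_voxel, delta_f_hz,
                               seed = 1L) {
  if (n_per_voxel < 1) stop("n_per_voxel must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  n <- n_per_voxel * n_voxels
  f <- switch(dist$name,
    gaussian = rnorm(n, sd = dist$sigma_hz),
    uniform = runif(n, dist$min_hz, dist$max_hz),
    stop("unknown frequency distribution: ", dist$name))
  f <- matrix(f, n_per_voxel, n_voxels)
  structure(list(f = f, f_delta = f + delta_f_hz, dist = dist,
                 delta_f_hz = delta_f_hz, seed = as.integer(seed)),
            class = "frequency_samples")
}

# wrap to (-pi, pi]
.wrap_pi <- function(x) atan2(sin(x), cos(x))

#' Normalized phase-consistency residual
#'
#' The phase difference between the responses at `f` and `f + delta_f`
#' must match free precession over half the pulse duration:
#' `phi(f) - phi(f + delta_f) = pi * delta_f * T`. The residual is the
#' wrapped deviation divided by `pi * delta_f * T`.
#'
#' @param phi_f Phase at offset `f` (rad).
#' @param phi_fd Phase at `f + delta_f` (rad).
#' @param delta_f_hz Pairing shift (Hz).
#' @param duration_s Total pulse duration T (s).
#' @return Unitless residual(s).
#' @export
phase_residual <- function(phi_f, phi_fd, delta_f_hz, duration_s) {
  target <- pi * delta_f_hz * duration_s
  if (target == 0) stop("delta_f * T must be nonzero")
  .wrap_pi(phi_f - phi_fd - target) / target
}

#' Region-of-interest weight for slice-specific designs
#'
#' Exponential decay `exp(-d / decay_mm)` with the distance `d` of a voxel
#' from the slice centre; 10 mm decay keeps nearby slices usable while
#' focusing the optimization.
#'
#' @param distance_mm Non-negative distance(s) from the slice centre (mm).
#' @param decay_mm Decay constant (mm).
#' @return Weight(s) in (0, 1].
#' @export
roi_weight <- function(distance_mm, decay_mm = 10) {
  if (any(distance_mm < 0)) stop("distance must be >= 0")
  exp(-distance_mm / decay_mm)
}

# ---------------------------------------------------------------------
# cost assembly (shared by the public evaluator and the optimizer)
#
# subjects: list of list(sens = complex Nv x Nc, db0 = Nv, pos = Nv x 3)
# samples:  list of frequency_samples, one per subject (columns = voxels)
# roi:      NULL or list of per-voxel weights per subject
# Returns mls/phase/total (normalized by the count of (subject, voxel, f)
# terms) and, when want_grad, d(total)/d(rf) and d(total)/d(grad).
.cost_eval <- function(rf, grad, dt, subjects, samples, spec, cfg,
                       roi = NULL, want_grad = FALSE) {
  nt <- ncol(rf)
  duration <- nt * dt
  fat0 <- spec$fa_deg
  pdt <- pi * cfg$delta_f_hz * duration
  k_wph <- .wph_k(spec, cfg)
  wph_c <- cfg$wph_center_frac * spec$fa_deg

  n_terms <- 0L
  mls_sum <- 0
  ph_sum <- 0
  if (want_grad) {
    Grf <- matrix(0i, nrow(rf), nt)
    Ggrad <- matrix(0, 3, nt)
  }

  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    smp <- samples[[s]]
    nv <- nrow(sub$sens)
    if (ncol(smp$f) != nv)
      stop("frequency samples do not cover every masked voxel of subject ", s)
    npf <- nrow(smp$f)
    ns1 <- npf * nv
    vi <- rep(seq_len(nv), each = npf)
    fvec <- as.vector(smp$f)
    fdvec <- as.vector(smp$f_delta)
    roiw <- if (is.null(roi)) rep(1, nv) else roi[[s]]

    B1vox <- sub$sens %*% rf                # Nv x Nt complex
    gpos <- sub$pos %*% grad                # Nv x Nt
    vi2 <- c(vi, vi)
    fall <- c(fvec, fdvec)
    B1 <- B1vox[vi2, , drop = FALSE]
    Om <- (sub$db0[vi2] + fall) +
      GAMMA_BAR_HZ_PER_MTM_MM * gpos[vi2, , drop = FALSE]

    # weights use the f draw of each pair (single-sample weight)
    w <- weight_profile(fvec, spec, cfg) *
      (1 + cfg$lambda_b0 * abs(sub$db0[vi])) * roiw[vi]
    pb <- abs(fvec) <= spec$bandwidth_hz / 2

    if (!want_grad) {
      M <- .bloch_batch(B1, Om, dt)
      fp <- flip_angle_and_phase(M)
      fa1 <- fp$fa_deg[seq_len(ns1)]
      res1 <- (fa1 - target_fa(fvec, spec)) / fat0
      mls_sum <- mls_sum + sum(w * res1^2)
      if (any(pb) && cfg$lambda_ph > 0) {
        pr <- phase_residual(fp$phase_rad[seq_len(ns1)][pb],
                             fp$phase_rad[ns1 + seq_len(ns1)][pb],
                             cfg$delta_f_hz, duration)
        wph <- weight_phase(fa1[pb], spec, cfg)
        ph_sum <- ph_sum + sum(wph * w[pb] * pr^2)
      }
    } else {
      # forward + adjoint seeds
      probe <- .bloch_batch(B1, Om, dt)
      mx <- probe[, 1]; my <- probe[, 2]; mz <- probe[, 3]
      p2 <- mx^2 + my^2
      p <- sqrt(p2)
      nrm <- p2 + mz^2
      fa <- atan2(p, mz) * 180 / pi
      ph <- ifelse(p < 1e-12, 0, atan2(my, mx))
      deg <- 180 / pi
      safe_p <- pmax(p, 1e-12)
      dfa_dmx <- deg * mz * mx / (safe_p * nrm)
      dfa_dmy <- deg * mz * my / (safe_p * nrm)
      dfa_dmz <- -deg * p / nrm
      dph_dmx <- ifelse(p < 1e-12, 0, -my / p2)
      dph_dmy <- ifelse(p < 1e-12, 0, mx / p2)

      fa1 <- fa[seq_len(ns1)]
      res1 <- (fa1 - target_fa(fvec, spec)) / fat0
      mls_sum <- mls_sum + sum(w * res1^2)
      dC_dfa <- numeric(2L * ns1)
      dC_dph <- numeric(2L * ns1)
      dC_dfa[seq_len(ns1)] <- 2 * w * res1 / fat0
      if (any(pb) && cfg$lambda_ph > 0) {
        i1 <- which(pb)
        i2 <- ns1 + i1
        pr <- phase_residual(ph[i1], ph[i2], cfg$delta_f_hz, duration)
        th <- tanh(k_wph * (fa1[i1] - wph_c))
        wph <- 0.5 * (1 + th)
        dwph <- 0.5 * k_wph * (1 - th^2)
        ph_sum <- ph_sum + sum(wph * w[i1] * pr^2)
        lam <- cfg$lambda_ph
        dC_dfa[i1] <- dC_dfa[i1] + lam * w[i1] * dwph * pr^2
        dC_dph[i1] <- dC_dph[i1] + lam * wph * w[i1] * 2 * pr / pdt
        dC_dph[i2] <- dC_dph[i2] - lam * wph * w[i1] * 2 * pr / pdt
      }
      Mbar <- cbind(dC_dfa * dfa_dmx + dC_dph * dph_dmx,
                    dC_dfa * dfa_dmy + dC_dph * dph_dmy,
                    dC_dfa * dfa_dmz)
      vjp <- .bloch_batch_vjp(B1, Om, dt, Mbar)
      sRe <- Re(sub$sens)[vi2, , drop = FALSE]
      sIm <- Im(sub$sens)[vi2, , drop = FALSE]
      GVre <- t(crossprod(vjp$Gb1x, sRe) + crossprod(vjp$Gb1y, sIm))
      GVim <- t(-crossprod(vjp$Gb1x, sIm) + crossprod(vjp$Gb1y, sRe))
      Grf <- Grf + GVre + 1i * GVim
      Ggrad <- Ggrad + GAMMA_BAR_HZ_PER_MTM_MM *
        crossprod(sub$pos[vi2, , drop = FALSE], vjp$Gom)
    }
    n_terms <- n_terms + ns1
  }

  mls_term <- mls_sum / n_terms
  phase_term <- ph_sum / n_terms
  total <- sqrt(mls_term + cfg$lambda_ph * phase_term)
  out <- list(mls_term = mls_term, phase_term = phase_term, total = total,
              n_terms = n_terms)
  if (want_grad) {
    # d sqrt(Craw / N) = dCraw / (2 * sqrt(Craw * N))
    scl <- if (total > 0) 1 / (2 * total * n_terms) else 0
    out$grad_rf <- Grf * scl
    out$grad_grad <- Ggrad * scl
  }
  class(out) <- "cost_breakdown"
  out
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "<cost_breakdown> total %.6g (mls %.3g, phase %.3g, %d terms)\n",
    x$total, x$mls_term, x$phase_term, x$n_terms))
  invisible(x)
}

#' Universal design cost over a cohort
#'
#' Evaluates the design cost: a weighted magnitude-least-squares term on
#' the flip angle against the rectangular target, plus `lambda_ph` times
#' the phase-consistency term over the passband pairs, each term
#' normalized by the total number of (subject, voxel, f) samples, combined
#' as `c = sqrt(mls + lambda_ph * phase)`. Flip angles and phases come
#' from hard-pulse Bloch simulations at every sampled offset `f` and its
#' partner `f + delta_f`.
#'
#' @param pulse A [pulse_waveforms()] object.
#' @param cohort List of `subject_fieldmap` objects (or of masked-voxel
#'   lists as returned by [fieldmap_voxels()]).
#' @param samples List of [sample_frequencies()] objects, one per subject,
#'   with one column per masked voxel.
#' @param spec A [target_spec()].
#' @param cfg A [weighting_config()].
#' @param roi Optional list of per-voxel ROI weights per subject (see
#'   [roi_weight()]).
#' @return A `cost_breakdown` with `mls_term`, `phase_term`, `total`.
#' @export
pulse_cost <- function(pulse, cohort, samples, spec,
                       cfg = weighting_config(), roi = NULL) {
  stopifnot(inherits(pulse, "pulse_waveforms"))
  subjects <- lapply(cohort, function(s)
    if (inherits(s, "subject_fieldmap")) fieldmap_voxels(s) else s)
  .cost_eval(pulse$rf, pulse$grad, pulse$dt, subjects, samples, spec, cfg,
             roi = roi, want_grad = FALSE)
}
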