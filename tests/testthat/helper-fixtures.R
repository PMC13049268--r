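# Shared fixtures and independent oracles for the test suite.

# unit-sensitivity CP reference voxel (all channels coherent)
ref_sens <- function(nc = 8, s = 11.75) rep(complex(real = s), nc)

# small, fast cohort configuration (coarse grid, full-size head)
small_cohort_config <- function(n_subjects = 2, master_seed = 42L) {
  cohort_config(n_subjects = n_subjects, grid_dim = c(10L, 9L, 8L),
                spacing_mm = 12, master_seed = master_seed)
}

# masked-voxel subsample of one default-resolution synthetic subject,
# the scaled-down slab design input
slab_subject <- function(n_voxels = 200, seed = 1L) {
  cc <- cohort_config(n_subjects = 1L, master_seed = seed)
  v <- fieldmap_voxels(generate_subject(cc, 1))
  set.seed(seed + 17L)
  keep <- sort(sample(nrow(v$sens), n_voxels))
  list(sens = v$sens[keep, ], db0 = v$db0[keep], pos = v$pos[keep, ])
}

slab_design_config <- function(seed = 1L, max_iter = 300L) {
  design_config(
    target = target_spec(90, 2500),
    weighting = weighting_config(lambda_ph = 3, lambda_b0 = 0.01,
                                 delta_f_hz = 100),
    duration_s = 3e-3, dt_coarse_s = 3e-5, dt_fine_s = 1e-5,
    max_iter = max_iter, seed = seed,
    freq_dist = list(name = "uniform", min_hz = -6250, max_hz = 6250),
    n_freq_per_voxel = 3L)
}

# the scaled-down constrained slab design, computed once per session
.design_cache <- new.env(parent = emptyenv())
get_slab_design <- function() {
  if (is.null(.design_cache$res)) {
    sub <- slab_subject(200, seed = 1L)
    .design_cache$sub <- sub
    .design_cache$res <- design_pulse(slab_design_config(seed = 1L),
                                      list(sub))
  }
  list(res = .design_cache$res, sub = .design_cache$sub)
}

# independent axis-angle rotation oracle: rotate m by the exact rotation
# generated by effective field (b1x, b1y, om) in Hz over dt seconds,
# using the package's handedness (a = -2*pi*dt*f_vec)
rot_oracle <- function(m, b1x, b1y, om, dt) {
  a <- -2 * pi * dt * c(b1x, b1y, om)
  th <- sqrt(sum(a^2))
  if (th == 0) return(m)
  u <- a / th
  uxm <- c(u[2] * m[3] - u[3] * m[2],
           u[3] * m[1] - u[1] * m[3],
           u[1] * m[2] - u[2] * m[1])
  m * cos(th) + uxm * sin(th) + u * sum(u * m) * (1 - cos(th))
}

# isochromat-ensemble oracle for the EPG: nspin spins uniformly dephased
# by one "unit" per half echo spacing, hard RF rotations in the package's
# convention (pulse phase phi rotates about (-cos phi, -sin phi, 0)),
# relaxation between events
iso_oracle <- function(exc_fa, exc_ph, cfg, nspin = 512) {
  th <- 2 * pi * (seq_len(nspin) - 0.5) / nspin - pi
  rot <- function(M, ang, phi) {
    u <- c(-cos(phi), -sin(phi), 0)
    ca <- cos(ang); sa <- sin(ang)
    uxv <- cbind(u[2] * M[, 3], -u[1] * M[, 3],
                 u[1] * M[, 2] - u[2] * M[, 1])
    udv <- M[, 1] * u[1] + M[, 2] * u[2]
    M * ca + uxv * sa + outer(udv * (1 - ca), u)
  }
  relax <- function(M, tau) {
    e2 <- if (is.finite(cfg$t2_ms)) exp(-tau / cfg$t2_ms) else 1
    e1 <- if (is.finite(cfg$t1_ms)) exp(-tau / cfg$t1_ms) else 1
    M[, 1:2] <- M[, 1:2] * e2
    M[, 3] <- M[, 3] * e1 + (1 - e1)
    M
  }
  dephase <- function(M) {
    x <- M[, 1] * cos(th) + M[, 2] * sin(th)
    y <- -M[, 1] * sin(th) + M[, 2] * cos(th)
    cbind(x, y, M[, 3])
  }
  M <- matrix(rep(c(0, 0, 1), each = nspin), nspin)
  M <- rot(M, exc_fa * pi / 180, exc_ph)
  out <- complex(length(cfg$flips_deg))
  for (k in seq_along(cfg$flips_deg)) {
    M <- relax(M, cfg$esp_ms[k] / 2)
    M <- dephase(M)
    M <- rot(M, cfg$flips_deg[k] * pi / 180, cfg$phases_rad[k])
    M <- relax(M, cfg$esp_ms[k] / 2)
    M <- dephase(M)
    out[k] <- mean(complex(real = M[, 1], imaginary = M[, 2]))
  }
  out
}
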