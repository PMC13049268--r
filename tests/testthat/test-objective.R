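spec0 <- target_spec(20, 3300)
cfg0 <- weighting_config(lambda_ph = 3, lambda_b0 = 0.02, delta_f_hz = 100)

test_that("target profile is a closed rectangular box", {
  expect_equal(target_fa(0, spec0), 20)
  expect_equal(target_fa(3300 / 2, spec0), 20)     # closed boundary
  expect_equal(target_fa(3300 / 2 + 1e-9, spec0), 0)
  expect_equal(target_fa(3300, spec0), 0)
  expect_equal(target_fa(c(-1650, -1651), spec0), c(20, 0))
})

test_that("profile weight has unit passband, zero edges, stopband plateau", {
  expect_equal(weight_profile(0, spec0, cfg0), 1)
  expect_equal(weight_profile(c(-1650, 1650), spec0, cfg0), c(0, 0))
  expect_equal(weight_profile(5000, spec0, cfg0), cfg0$stopband_weight)
  # continuity across the transition band
  f <- seq(0, 4000, by = 1)
  w <- weight_profile(f, spec0, cfg0)
  expect_lt(max(abs(diff(w))), 0.01)
  expect_true(all(w >= 0))
})

test_that("voxel weight combines profile and |deltaB0| linearly", {
  expect_equal(weight_voxel(0, 500, cfg0, spec0),
               weight_profile(500, spec0, cfg0))
  cfg_b0_off <- weighting_config(lambda_b0 = 0)
  expect_equal(weight_voxel(400, 500, cfg_b0_off, spec0),
               weight_profile(500, spec0, cfg_b0_off))
  expect_equal(weight_voxel(100, 0, cfg0, spec0), 3) # 1 + 0.02 * 100
  expect_equal(weight_voxel(-100, 0, cfg0, spec0), 3) # absolute value
})

test_that("phase gate is a tanh step centred at 20% of the target", {
  expect_equal(weight_phase(0.2 * 20, spec0, cfg0), 0.5)
  expect_gt(weight_phase(20, spec0, cfg0), 0.99)
  expect_lt(weight_phase(0, spec0, cfg0), 0.05)
  fa <- seq(0, 25, by = 0.5)
  expect_true(all(diff(weight_phase(fa, spec0, cfg0)) > 0))
})

test_that("frequency sampling is seeded, per-voxel unique, and calibrated", {
  s <- sample_frequencies(12000, list(name = "gaussian", sigma_hz = 6600),
                          5, 100, seed = 3)
  expect_equal(dim(s$f), c(5, 12000))
  expect_equal(sd(as.vector(s$f)), 6600, tolerance = 0.02)
  expect_equal(s$f_delta, s$f + 100)
  expect_false(isTRUE(all.equal(s$f[, 1], s$f[, 2])))
  expect_identical(s$f,
                   sample_frequencies(12000,
                                      list(name = "gaussian",
                                           sigma_hz = 6600),
                                      5, 100, seed = 3)$f)
  u <- sample_frequencies(500, list(name = "uniform", min_hz = -6250,
                                    max_hz = 6250), 3, 100, seed = 1)
  expect_true(all(u$f >= -6250 & u$f <= 6250))
  expect_error(sample_frequencies(10, list(name = "cauchy"), 3, 100),
               "unknown")
})

test_that("phase residual matches the free-precession model and wraps", {
  T <- 3e-3
  f <- c(-500, 0, 700)
  expect_equal(phase_residual(-pi * f * T, -pi * (f + 100) * T, 100, T),
               rep(0, 3))
  expect_equal(phase_residual(0, 0, 100, 3e-3), -1) # constant phase
  r1 <- phase_residual(0.3, -0.2, 100, T)
  expect_equal(phase_residual(0.3 + 2 * pi, -0.2, 100, T), r1)
  expect_equal(phase_residual(0.3, -0.2 - 2 * pi, 100, T), r1)
})

test_that("ROI weight decays exponentially over 10 mm", {
  expect_equal(roi_weight(0), 1)
  expect_equal(roi_weight(10), exp(-1))
  d <- seq(0, 50, by = 5)
  expect_true(all(diff(roi_weight(d)) < 0))
  expect_error(roi_weight(-1), ">= 0")
})

test_that("cohort cost matches an independent straight-loop evaluation", {
  set.seed(21)
  nc <- 3; nv <- 4; nt <- 12; dt <- 3e-5
  subjects <- lapply(1:2, function(i)
    list(sens = matrix(complex(real = rnorm(nv * nc, sd = 8),
                               imaginary = rnorm(nv * nc, sd = 8)), nv),
         db0 = rnorm(nv, sd = 120),
         pos = matrix(rnorm(nv * 3, sd = 25), nv)))
  samples <- lapply(1:2, function(i)
    sample_frequencies(nv, list(name = "gaussian", sigma_hz = 2500),
                       2, 100, seed = 30 + i))
  rf <- matrix(complex(real = rnorm(nc * nt, sd = 0.5),
                       imaginary = rnorm(nc * nt, sd = 0.5)), nc)
  gr <- matrix(rnorm(3 * nt, sd = 4), 3)
  pulse <- pulse_waveforms(rf, gr, dt)
  roi <- lapply(1:2, function(i) runif(nv, 0.3, 1))

  got <- pulse_cost(pulse, subjects, samples, spec0, cfg0, roi = roi)

  # brute force: explicit loops over subjects, voxels and offsets
  T <- nt * dt
  mls <- 0; phs <- 0; nterms <- 0
  for (s in 1:2) {
    sub <- subjects[[s]]
    for (v in 1:nv) {
      for (k in 1:2) {
        f <- samples[[s]]$f[k, v]
        fd <- samples[[s]]$f_delta[k, v]
        st <- simulate_voxel(pulse, sub$sens[v, ], sub$db0[v], sub$pos[v, ], f)
        fp <- flip_angle_and_phase(st)
        std <- simulate_voxel(pulse, sub$sens[v, ], sub$db0[v], sub$pos[v, ], fd)
        fpd <- flip_angle_and_phase(std)
        w <- weight_voxel(sub$db0[v], f, cfg0, spec0) * roi[[s]][v]
        mls <- mls + w * ((fp$fa_deg - target_fa(f, spec0)) / 20)^2
        if (abs(f) <= 3300 / 2) {
          pr <- phase_residual(fp$phase_rad, fpd$phase_rad, 100, T)
          phs <- phs + weight_phase(fp$fa_deg, spec0, cfg0) * w * pr^2
        }
        nterms <- nterms + 1
      }
    }
  }
  expect_equal(got$mls_term, mls / nterms, tolerance = 1e-10)
  expect_equal(got$phase_term, phs / nterms, tolerance = 1e-10)
  expect_equal(got$total, sqrt(mls / nterms + 3 * phs / nterms),
               tolerance = 1e-10)
})

test_that("cost vanishes on a perfect response and grows with subjects", {
  # calibrated CP sinc nails FAT at f = 0 on the reference voxel
  p <- make_cp_sinc(20, 3e-3, 10, 8, dt = 3e-5)
  sub <- list(sens = matrix(ref_sens(), 1), db0 = 0,
              pos = matrix(0, 1, 3))
  smp <- sample_frequencies(1, list(name = "uniform", min_hz = 0,
                                    max_hz = 0), 1, 100, seed = 1)
  cfg_mls <- weighting_config(lambda_ph = 0, lambda_b0 = 0.02)
  c0 <- pulse_cost(p, list(sub), list(smp), spec0, cfg_mls)
  expect_lt(c0$total, 1e-6)
  expect_equal(c0$total, sqrt(c0$mls_term)) # lambda_ph = 0: pure MLS

  # adding a subject can only increase the unnormalized residual sum
  sub2 <- list(sens = matrix(0.7 * ref_sens(), 1), db0 = 50,
               pos = matrix(0, 1, 3))
  c1 <- pulse_cost(p, list(sub2), list(smp), spec0, cfg_mls)
  c2 <- pulse_cost(p, list(sub2, sub2), list(smp, smp), spec0, cfg_mls)
  expect_gte(c2$n_terms * c2$total^2, c1$n_terms * c1$total^2 - 1e-12)
  expect_gte(c1$total, 0)
})

test_that("symmetric small-tip pulses have a negligible phase term", {
  p <- make_cp_sinc(2, 3e-3, 10, 8, dt = 1e-5)
  nvx <- 5
  set.seed(9)
  sub <- list(sens = outer(runif(nvx, 0.6, 1.1), ref_sens()),
              db0 = rep(0, nvx), pos = matrix(0, nvx, 3))
  smp <- sample_frequencies(nvx, list(name = "uniform", min_hz = -1200,
                                      max_hz = 1200), 3, 100, seed = 2)
  spec_small <- target_spec(2, 3300)
  cb <- pulse_cost(p, list(sub), list(smp), spec_small, cfg0)
  expect_lt(cb$phase_term, 1e-4)
})

test_that("analytic cost gradient agrees with finite differences", {
  set.seed(33)
  nc <- 2; nv <- 3; nt <- 8; dt <- 3e-5
  sub <- list(sens = matrix(complex(real = rnorm(nv * nc, sd = 8),
                                    imaginary = rnorm(nv * nc, sd = 8)), nv),
              db0 = rnorm(nv, sd = 100),
              pos = matrix(rnorm(nv * 3, sd = 25), nv))
  smp <- sample_frequencies(nv, list(name = "gaussian", sigma_hz = 2000),
                            2, 100, seed = 4)
  rf <- matrix(complex(real = rnorm(nc * nt, sd = 0.6),
                       imaginary = rnorm(nc * nt, sd = 0.6)), nc)
  gr <- matrix(rnorm(3 * nt, sd = 3), 3)
  ce <- ptxgrape:::.cost_eval(rf, gr, dt, list(sub), list(smp), spec0,
                              cfg0, want_grad = TRUE)
  f0 <- function(rf, gr)
    ptxgrape:::.cost_eval(rf, gr, dt, list(sub), list(smp), spec0,
                          cfg0)$total
  eps <- 1e-5
  num <- function(widx, part) {
    d <- matrix(0, if (part == "g") 3 else nc, nt)
    d[widx] <- eps
    switch(part,
      re = (f0(rf + d, gr) - f0(rf - d, gr)) / (2 * eps),
      im = (f0(rf + 1i * d, gr) - f0(rf - 1i * d, gr)) / (2 * eps),
      g = (f0(rf, gr + d) - f0(rf, gr - d)) / (2 * eps))
  }
  set.seed(7)
  for (widx in sample(nc * nt, 6)) {
    expect_equal(num(widx, "re"), Re(ce$grad_rf[widx]), tolerance = 1e-5)
    expect_equal(num(widx, "im"), Im(ce$grad_rf[widx]), tolerance = 1e-5)
  }
  for (widx in sample(3 * nt, 4))
    expect_equal(num(widx, "g"), ce$grad_grad[widx], tolerance = 1e-5)
})
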