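test_that("hard-pulse propagation matches the closed-form rotation oracle", {
  set.seed(11)
  dt <- 1e-5
  for (i in 1:20) {
    b1 <- complex(real = rnorm(1, sd = 300), imaginary = rnorm(1, sd = 300))
    om <- rnorm(1, sd = 3000)
    p <- pulse_waveforms(matrix(b1 / 11.75, 1, 2), matrix(0, 3, 2), dt)
    st <- simulate_voxel(p, 11.75 + 0i, db0_hz = om)
    m <- c(0, 0, 1)
    m <- rot_oracle(m, Re(b1), Im(b1), om, dt)
    m <- rot_oracle(m, Re(b1), Im(b1), om, dt)
    expect_lt(max(abs(c(st$mx, st$my, st$mz) - m)), 1e-10)
    expect_lt(abs(st$mx^2 + st$my^2 + st$mz^2 - 1), 1e-9)
  }
  # composition of constant samples equals a single rotation over n*dt
  p10 <- pulse_waveforms(matrix(8 + 3i, 1, 10), matrix(0, 3, 10), dt)
  st <- simulate_voxel(p10, 11.75 + 0i, db0_hz = 500)
  m1 <- rot_oracle(c(0, 0, 1), 11.75 * 8, 11.75 * 3, 500, 10 * dt)
  expect_lt(max(abs(c(st$mx, st$my, st$mz) - m1)), 1e-10)
})

test_that("equilibrium, nutation and FA/phase extraction behave as closed forms", {
  # zero RF at any offset: nothing happens
  z <- pulse_waveforms(matrix(0i, 2, 50), matrix(0, 3, 50), 1e-5)
  st <- simulate_voxel(z, c(5 + 1i, 3 - 2i), db0_hz = 1234)
  expect_equal(c(st$mx, st$my, st$mz), c(0, 0, 1))
  # constant on-resonance b1 with integral pi/2: full transverse
  nt <- 100; dt <- 1e-5
  b1 <- 0.25 / (nt * dt)            # cycles: 2*pi*b1*T = pi/2
  p <- pulse_waveforms(matrix(b1, 1, nt), matrix(0, 3, nt), dt)
  st <- simulate_voxel(p, 1 + 0i)
  expect_equal(sqrt(st$mx^2 + st$my^2), 1, tolerance = 1e-10)
  expect_equal(st$mz, 0, tolerance = 1e-10)

  expect_equal(flip_angle_and_phase(magnetization_state(0, 0, 1)),
               list(fa_deg = 0, phase_rad = 0))
  expect_equal(flip_angle_and_phase(magnetization_state(1, 0, 0)),
               list(fa_deg = 90, phase_rad = 0))
  fp <- flip_angle_and_phase(magnetization_state(0, sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(fp$fa_deg, 45)
  expect_equal(fp$phase_rad, pi / 2)
})

test_that("small-tip regime is linear and Fourier-like", {
  sref <- ref_sens()
  p2 <- make_cp_sinc(2, 3e-3, 10, 8, dt = 1e-5)
  p1 <- make_cp_sinc(1, 3e-3, 10, 8, dt = 1e-5)
  f <- seq(-1500, 1500, by = 100)
  r2 <- spectral_response(p2, sref, freqs = f)
  r1 <- spectral_response(p1, sref, freqs = f)
  expect_lt(max(abs(r2$fa_deg / 2 - r1$fa_deg) / r1$fa_deg), 0.01)

  # FA(f) proportional to |FT of envelope| within 2% across the passband
  env <- Re(p2$rf[1, ]) * 8 * 11.75
  tt <- (seq_along(env) - (length(env) + 1) / 2) * p2$dt
  ft <- vapply(f, function(ff)
    Mod(sum(env * exp(-2i * pi * ff * tt) * p2$dt)), numeric(1))
  pred <- 360 * ft  # degrees, small-tip
  expect_lt(max(abs(r2$fa_deg - pred) / pred), 0.02)
})

test_that("time symmetry gives linear spectral phase with slope -pi*T", {
  wdiff <- function(x) atan2(sin(diff(x)), cos(diff(x)))
  p <- make_cp_sinc(2, 3e-3, 10, 8, dt = 1e-5)
  f <- seq(-1200, 1200, by = 100)
  r <- spectral_response(p, ref_sens(), freqs = f)
  slopes <- wdiff(r$phase_rad) / diff(f)
  expect_lt(max(abs(slopes + pi * p$duration)), 1e-3 * pi * p$duration)
  # a time-mirrored asymmetric pulse negates the envelope phase slope, so
  # the two slopes sum to twice the free-precession slope -pi*T
  set.seed(3)
  rf <- matrix(complex(real = rnorm(60, sd = 0.02),
                       imaginary = rnorm(60, sd = 0.02)), 1)
  pa <- pulse_waveforms(rf, matrix(0, 3, 60), 1e-5)
  pb <- pulse_waveforms(rf[, 60:1, drop = FALSE], matrix(0, 3, 60), 1e-5)
  ra <- spectral_response(pa, 11.75 + 0i, freqs = f)
  rb <- spectral_response(pb, 11.75 + 0i, freqs = f)
  sa <- mean(wdiff(ra$phase_rad)) / 100
  sb <- mean(wdiff(rb$phase_rad)) / 100
  expect_equal(sa + sb, -2 * pi * pa$duration, tolerance = 1e-2)
})

test_that("slice profiles map bandwidth to thickness through the gradient", {
  # selection gradient for 3.3 kHz bandwidth and 1.5 mm slice
  g_sel <- 3300 / (42.577 * 1.5)
  expect_equal(g_sel, 51.7, tolerance = 0.002)
  p <- make_cp_sinc(20, 3e-3, 10, 8, dt = 1e-5)
  cfg <- profile_config(n_spins = 600, length_mm = 6, g_sel_mtm = g_sel)
  prof <- slice_profile(p, ref_sens(), 0, cfg)
  amp <- Mod(prof$mxy)
  half <- max(amp) / 2
  above <- which(amp >= half)
  fwhm_mm <- prof$x_mm[max(above)] - prof$x_mm[min(above)]
  expect_equal(fwhm_mm, 1.5, tolerance = 0.1)
  # zero RF: zero profile
  z <- pulse_waveforms(matrix(0i, 8, 50), matrix(0, 3, 50), 1e-5)
  expect_true(all(Mod(slice_profile(z, ref_sens(), 0, cfg)$mxy) == 0))
})

test_that("slice integral is phase-sensitive and matches quadrature", {
  n <- 200
  sp <- 6 / (n - 1)
  uniform <- rep(0.5 + 0i, n)
  expect_equal(slice_integral(uniform, sp), 0.5 * sp * n, tolerance = 1e-12)
  ramp <- 0.5 * exp(2i * pi * seq(0, 1, length.out = n))
  expect_lt(slice_integral(ramp, sp), 0.01 * slice_integral(uniform, sp))
  set.seed(8)
  arb <- complex(real = rnorm(n), imaginary = rnorm(n))
  expect_equal(slice_integral(arb, sp), Mod(sum(arb)) * sp, tolerance = 1e-12)
  expect_error(slice_integral(1 + 0i, 1), "2 spins")
})
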