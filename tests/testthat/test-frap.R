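test_that("double normalization reproduces the defining arithmetic", {
  t <- 0:3
  rec <- frap_record(t, I_ROI = c(100, 100, 50, 80), I_ref = c(80, 80, 40, 80))
  rec <- double_normalize(rec)
  expect_equal(rec$I_norm[1], 1)              # pre-bleach anchor
  expect_equal(rec$I_norm[2], 1)              # unchanged frame
  expect_equal(rec$I_norm[3], (50 / 100) * (80 / 40)) # = 1.0
  expect_error(frap_record(t, c(1, 1, 1, 1), c(1, 0, 1, 1)), "positive")
})

test_that("double normalization is invariant to common multiplicative drift", {
  set.seed(3)
  t <- seq(0, 300, 2)
  roi <- 0.2 + 0.8 * (1 - exp(-t / 40)) + 0.01 * rnorm(length(t))
  ref <- 1 + 0.05 * rnorm(length(t))
  roi[1] <- 1
  ref <- abs(ref) + 0.1
  base <- double_normalize(frap_record(t, roi, ref))$I_norm
  for (rate in c(1e-4, 1e-3)) {
    drift <- exp(-rate * t)
    drifted <- double_normalize(frap_record(t, roi * drift, ref * drift))$I_norm
    expect_equal(drifted, base, tolerance = 1e-14)
  }
})

test_that("half-recovery time reads exponential recoveries and the arrested convention", {
  t <- seq(0, 400, 0.5)
  curve <- 1 - 0.8 * exp(-t * log(2) / 30)
  r <- half_recovery_time(curve, times = t)
  expect_equal(r$t_half, 30, tolerance = 0.02)
  expect_false(r$arrested)

  # flat at the floor: arrested, reported at the observation horizon
  flat <- c(1, rep(0.2, 500))
  r2 <- half_recovery_time(flat, times = seq(0, 6000, length.out = 501), T_max = 6000)
  expect_equal(r2$t_half, 6000)
  expect_true(r2$arrested)

  # partial recovery to plateau 0.6 from floor 0.2: midpoint 0.4 at t = t_half
  th <- 52.3
  curve3 <- 0.2 + 0.4 * (1 - exp(-t * log(2) / th))
  r3 <- half_recovery_time(curve3, times = t)
  expect_equal(r3$t_half, th, tolerance = 0.05)
})

test_that("gaussian_sigma2 recovers variances from clean and noisy profiles", {
  x <- seq(-10, 10, 0.1)
  prof <- 2 * exp(-(x - 1)^2 / (2 * 4)) + 0.5
  expect_equal(as.numeric(gaussian_sigma2(prof, x)), 4, tolerance = 1e-6)

  set.seed(5)
  noisy <- prof * (1 + 0.01 * rnorm(length(x)))
  expect_equal(as.numeric(gaussian_sigma2(noisy, x)), 4, tolerance = 0.1)

  # a dip fits just as well (negative amplitude)
  dip <- 1 - 0.6 * exp(-x^2 / (2 * 2.25))
  expect_equal(as.numeric(gaussian_sigma2(dip, x)), 2.25, tolerance = 1e-6)

  expect_error(gaussian_sigma2(rep(1, 50), seq_len(50)), "flat")
})

test_that("diffusion coefficient equals half the variance slope", {
  t <- 0:19
  s2 <- 1 + 2 * 0.5 * t
  fit <- fit_diffusion_coefficient(list(times = t, sigma2 = s2))
  expect_equal(fit$D, 0.5, tolerance = 1e-12)
  fit0 <- fit_diffusion_coefficient(list(times = t, sigma2 = rep(2, 20)))
  expect_equal(fit0$D, 0, tolerance = 1e-12)
  expect_error(fit_diffusion_coefficient(list(times = 1:2, sigma2 = c(1, 2))),
               "3 frames")
})

test_that("closed loop: synthetic FRAP series round-trips the half time", {
  g <- gen_frap_series(t_half = 45, floor = 0.2, plateau = 1, T_max = 300)
  r <- half_recovery_time(g$record)
  expect_equal(r$t_half, 45, tolerance = 0.02 * 45)
  expect_false(r$arrested)

  # global acquisition bleaching leaves the recovered time unchanged
  gb <- gen_frap_series(t_half = 45, floor = 0.2, plateau = 1, T_max = 300,
                        global_bleach_rate = 2e-3)
  rb <- half_recovery_time(gb$record)
  expect_equal(rb$t_half, r$t_half, tolerance = 1e-10)

  # arrested input: the 6000 s convention, exactly
  ga <- gen_frap_series(t_half = Inf, floor = 0.2, plateau = 1, T_max = 6000)
  ra <- half_recovery_time(ga$record)
  expect_identical(ra$arrested, TRUE)
  expect_equal(ra$t_half, 6000)
})

test_that("closed loop: point-bleach stacks round-trip D", {
  g <- gen_pointbleach_stack(D = 1, sigma0 = 1, n_frames = 20, dt = 1,
                             noise = list(type = "gaussian", sigma_rel = 0.01),
                             seed = 2)
  fit <- fit_diffusion_coefficient(g$series)
  expect_equal(fit$D, 1, tolerance = 0.05)

  g0 <- gen_pointbleach_stack(D = 0, sigma0 = 1.5, n_frames = 10, dt = 1)
  fit0 <- fit_diffusion_coefficient(g0$series)
  expect_equal(fit0$D, 0, tolerance = 1e-8)
  expect_equal(fit0$sigma2, rep(1.5^2, 10), tolerance = 1e-6)
})

test_that("arrested and dynamic records differ by orders of magnitude in 1/t_half", {
  dyn <- half_recovery_time(gen_frap_series(t_half = 50, T_max = 300)$record)
  arr <- half_recovery_time(gen_frap_series(t_half = Inf, T_max = 6000)$record)
  expect_gte((1 / dyn$t_half) / (1 / arr$t_half), 100)
})
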