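test_that("detect_front finds steps, peaks and the erfc half-rise point", {
  x <- seq(0, 10, 0.05)
  step <- ifelse(x < 5, 1, 0)
  expect_equal(detect_front(step, x, "half_rise"), 5, tolerance = 0.05)

  bump <- 1 + 2 * exp(-(x - 3)^2 / (2 * 0.5^2))
  expect_equal(detect_front(bump, x, "peak"), 3, tolerance = 1e-12)

  # half-rise of the constant-source profile: x* = 2 sqrt(D t) erfc^-1(1/2)
  x2 <- seq(0, 20, 0.01)
  prof <- erfc_num(x2 / (2 * sqrt(1 * 4)))
  z_half <- uniroot(function(z) erfc_num(z) - 0.5, c(0.1, 1), tol = 1e-12)$root
  expect_equal(detect_front(prof, x2, "half_rise"), 2 * sqrt(4) * z_half,
               tolerance = 1e-3)
  expect_equal(2 * sqrt(4) * z_half, 1.9077, tolerance = 1e-3)

  expect_true(is.na(detect_front(rep(2, 50), seq_len(50))))
})

test_that("detect_front is equivariant to affine intensity rescaling", {
  x <- seq(0, 10, 0.02)
  set.seed(42)
  for (i in 1:10) {
    xf <- runif(1, 2, 8)
    prof <- 1 / (1 + exp((x - xf) / 0.2)) + 0.02 * rnorm(length(x))
    a <- runif(1, 0.1, 50); b <- runif(1, -5, 5)
    for (conv in c("half_rise", "peak")) {
      p0 <- detect_front(prof, x, conv)
      p1 <- detect_front(a * prof + b, x, conv)
      expect_equal(p1, p0, tolerance = 1e-12)
    }
  }
})

test_that("front_width matches analytic widths", {
  x <- seq(-10, 10, 0.01)
  # FWHM of a Gaussian peak: 2 sqrt(2 log 2) sigma
  g <- exp(-x^2 / (2 * 2^2))
  expect_equal(front_width(g, x), 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-3)

  # ideal step front: width collapses to the grid scale
  xs <- seq(0, 10, 0.1)
  step <- ifelse(xs < 5, 1, 0)
  expect_lte(front_width(step, xs), 2 * 0.1)

  # erfc profile: 16-84 rise distance against brute-force root finding
  xe <- seq(0, 30, 0.005)
  D <- 1; t <- 9
  prof <- erfc_num(xe / (2 * sqrt(D * t)))
  x16 <- uniroot(function(z) erfc_num(z / (2 * sqrt(D * t))) - 0.16, c(0, 30), tol = 1e-12)$root
  x84 <- uniroot(function(z) erfc_num(z / (2 * sqrt(D * t))) - 0.84, c(0, 30), tol = 1e-12)$root
  expect_equal(front_width(prof, xe), x16 - x84, tolerance = 1e-3)
})

test_that("peak_ratio reads the overshoot over the invaded plateau", {
  x <- seq(0, 10, 0.02)
  flat <- ifelse(x <= 6, 1, 0)
  expect_equal(peak_ratio(flat, x), 1.0)

  peaked <- ifelse(x <= 6, 1 + 1.5 * exp(-(x - 6)^2 / (2 * 0.3^2)), 0)
  expect_equal(peak_ratio(peaked, x), 2.5, tolerance = 1e-3)

  # front at the boundary: no plateau behind
  expect_error(peak_ratio(c(5, 1, 1, 1, 1), 1:5), "plateau")
})

test_that("front_trace rejects flat kymographs and tracks traveling fronts", {
  k <- kymograph(matrix(1, 10, 50), positions = seq(0, 10, length.out = 50),
                 times = 1:10)
  expect_error(front_trace(k), "insufficient|front")

  gen <- gen_ballistic_kymograph(v = 0.1, W = 1, peak_ratio = 2, L = 20,
                                 n_x = 800, n_t = 40, t_end = 150)
  tr <- front_trace(gen$kymograph, convention = "peak")
  fit <- fit_velocity(tr)
  expect_equal(fit$v, 0.1, tolerance = 0.01)
  # constant width along the trace (self-similar shape); skip the first
  # frames where the peak is still partly outside the domain
  Wmid <- tr$W[-(1:3)]
  expect_lt(stats::sd(Wmid, na.rm = TRUE) / mean(Wmid, na.rm = TRUE), 0.05)
})

test_that("scaling-exponent fits recover generating laws", {
  t <- seq(1, 100, length.out = 50)
  tr1 <- data.frame(t = t, X_front = 3 * t)
  expect_equal(fit_scaling_exponent(tr1)$alpha, 1, tolerance = 1e-10)
  tr2 <- data.frame(t = t, X_front = 2 * sqrt(t))
  expect_equal(fit_scaling_exponent(tr2)$alpha, 0.5, tolerance = 1e-10)

  set.seed(7)
  tr3 <- data.frame(t = t, X_front = 1.3 * t^0.75 * exp(0.01 * rnorm(50)))
  expect_equal(fit_scaling_exponent(tr3)$alpha, 0.75, tolerance = 0.03)

  tr4 <- data.frame(t = t, X_front = c(-1, 3 * t[-1]))
  expect_error(fit_scaling_exponent(tr4, window = range(t)), "non-positive")
})

test_that("velocity fits recover slopes within error", {
  t <- seq(0, 200, 4)
  expect_equal(fit_velocity(data.frame(t = t, X_front = 0.05 * t))$v, 0.05,
               tolerance = 1e-12)
  expect_equal(fit_velocity(data.frame(t = t, X_front = rep(2, length(t))))$v, 0,
               tolerance = 1e-12)
  set.seed(11)
  x <- 0.05 * t + 0.02 * diff(range(0.05 * t)) * rnorm(length(t))
  fit <- fit_velocity(data.frame(t = t, X_front = x))
  expect_lt(abs(fit$v - 0.05), 3 * fit$se)
  expect_error(fit_velocity(data.frame(t = 1:2, X_front = 1:2), window = c(0, 3)),
               "3 points")
})

test_that("log-log power-law fit is exact on exact laws", {
  x <- c(1, 2, 5, 10, 20)
  f <- scaling_law_fit(x, x^2)
  expect_equal(f$exponent, 2, tolerance = 1e-12)
  f2 <- scaling_law_fit(x, 3 * sqrt(x))
  expect_equal(f2$exponent, 0.5, tolerance = 1e-12)
  expect_equal(f2$prefactor, 3, tolerance = 1e-10)
  expect_equal(f2$r_squared, 1)
  expect_error(scaling_law_fit(c(-1, 2, 3), 1:3), "positive")
})

test_that("regime classification follows the alpha / peak-ratio rules", {
  expect_equal(classify_regime(alpha = 0.5, peak_ratio = 1.0), "fickian")
  expect_equal(classify_regime(alpha = 1.0, peak_ratio = 2.0), "ballistic_wave")
  expect_equal(classify_regime(alpha = 1.0, peak_ratio = 1.05), "ballistic_front")
  expect_error(classify_regime(list()), "front_analysis|finite")
})

test_that("front position and width converge as kymograph resolution doubles", {
  mk <- function(n_x) gen_ballistic_kymograph(v = 0.1, W = 1, peak_ratio = 2,
                                              L = 20, n_x = n_x, n_t = 30,
                                              t_end = 150)$kymograph
  k1 <- mk(400); k2 <- mk(800)
  dx1 <- diff(k1$positions[1:2])
  i <- 20
  p1 <- detect_front(k1$intensity[i, ], k1$positions, "peak")
  p2 <- detect_front(k2$intensity[i, ], k2$positions, "peak")
  expect_lt(abs(p1 - p2), dx1)
  w1 <- front_width(k1$intensity[i, ], k1$positions)
  w2 <- front_width(k2$intensity[i, ], k2$positions)
  expect_lt(abs(w1 - w2), dx1)
})
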