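test_that("initial state is uniform barcode, zero invader", {
  p <- model_params(m_total = 1, n_cells = 100, L = 7.5, t_end = 10, dt_out = 1)
  s <- initialize_state(p)
  conc <- state_concentrations(s, p)
  expect_equal(conc$m_free, rep(1, 100))          # 1 mM everywhere
  expect_equal(s$u, rep(0, 100))
  expect_equal(sum(s$m_free), p$m_total * p$L)    # total barcode amount (slab)
  expect_equal(s$w, rep(7.5 / 100, 100))
})

test_that("zero reservoir concentration leaves the state unchanged", {
  p <- tiny_params(u_res = 0)
  sim <- simulate_invasion(p)
  s <- sim$state
  expect_equal(s$u, rep(0, p$n_cells))
  expect_equal(s$M_arr, rep(0, p$n_cells))
  expect_equal(sum(s$m_free), p$m_total * p$L)
  expect_equal(s$influx, 0)
})

test_that("reaction step reproduces closed-form kinetics", {
  # pure swelling decay: M_arr(t) = A0 exp(-ks t), M_sw complements
  p <- tiny_params(k_bind = 0, k_swell = 0.05)
  s <- make_state(p, u = 0, m_free = 0, M_arr = 0.8)
  s2 <- reaction_step(s, p, dt = 30)
  vol <- s$w
  expect_equal(s2$M_arr / vol, rep(0.8 * exp(-0.05 * 30), p$n_cells), tolerance = 1e-12)
  expect_equal((s2$M_arr + s2$M_sw) / vol, rep(0.8, p$n_cells), tolerance = 1e-12)
  expect_equal(s2$u, s$u)

  # equal-concentration second-order binding: u(t) = u0 / (1 + k u0 t)
  p <- tiny_params(k_bind = 2e6, k_swell = 0)
  kmm <- p$k_bind * 1e-3 # 1/(mM s)
  s <- make_state(p, u = 1, m_free = 1)
  s2 <- reaction_step(s, p, dt = 5)
  expect_equal(s2$u / s$w, rep(1 / (1 + kmm * 1 * 5), p$n_cells), tolerance = 1e-10)

  # unequal concentrations against an independent RK4 oracle
  y <- rk4_reaction(u0 = 0.3, m0 = 1, Ma0 = 0.05, Ms0 = 0,
                    k_bind = kmm, k_swell = 0.01, t_end = 5)
  p2 <- tiny_params(k_bind = 2e6, k_swell = 0.01)
  s <- make_state(p2, u = 0.3, m_free = 1, M_arr = 0.05)
  s2 <- reaction_step(s, p2, dt = 5)
  got <- c(s2$u[1], s2$m_free[1], s2$M_arr[1], s2$M_sw[1]) / s$w[1]
  expect_equal(got, y, tolerance = 1e-4)
  expect_true(all(unlist(s2[c("u", "m_free", "M_arr", "M_sw")]) >= 0))
})

test_that("reaction step never produces negative species at huge dt", {
  p <- tiny_params(k_bind = 1e9, k_swell = 10)
  s <- make_state(p, u = 0.5, m_free = 1)
  s2 <- reaction_step(s, p, dt = 1e6)
  expect_true(all(unlist(s2[c("u", "m_free", "M_arr", "M_sw")]) >= -1e-15))
  # barcode pool conserved per cell
  tot0 <- s$m_free + s$M_arr + s$M_sw
  tot2 <- s2$m_free + s2$M_arr + s2$M_sw
  expect_equal(tot2, tot0, tolerance = 1e-12)
})

test_that("diffusivity switches on the swollen-fraction threshold", {
  p <- tiny_params(theta = 0.5)
  s <- make_state(p)                    # no swelling
  d <- diffusivity_field(s, p)
  expect_equal(d$D_cell, rep(p$D0, p$n_cells))
  s <- make_state(p, m_free = 0, M_sw = 1) # fully swollen
  expect_equal(diffusivity_field(s, p)$D_cell, rep(p$D1, p$n_cells))

  # adjacent cells at phi = 0.4 / 0.6: (D0, D1), harmonic interface
  s <- make_state(p, m_free = c(0.6, 0.4), M_sw = c(0.4, 0.6))
  d <- diffusivity_field(s, p)
  expect_equal(d$D_cell[1:2], c(p$D0, p$D1))
  expect_equal(d$D_interface[1], 2 * p$D0 * p$D1 / (p$D0 + p$D1))
})

test_that("swelling geometry follows the linear expansion convention", {
  p <- tiny_params(f_swell = 4)
  w0 <- p$L / p$n_cells
  s <- make_state(p)                      # phi = 0
  expect_equal(swelling_geometry_update(s, p)$w, rep(w0, p$n_cells))

  s <- make_state(p, m_free = 0, M_sw = 1) # phi = 1, 1D-volumetric: g = f_swell
  s2 <- swelling_geometry_update(s, p)
  expect_equal(s2$w, rep(4 * w0, p$n_cells))
  expect_equal(sum(s2$w), 4 * p$L)        # fourfold domain expansion
  conc <- state_concentrations(s2, p)     # fourfold dilution of the barcode pool
  expect_equal(conc$M_sw, rep(p$m_total / 4, p$n_cells))

  # phi = 0.5 in one cell: w = w0 * (1 + 1.5) = 2.5 w0
  s <- make_state(p, m_free = c(0.5, rep(1, p$n_cells - 1)),
                  M_sw = c(0.5, rep(0, p$n_cells - 1)))
  expect_equal(swelling_geometry_update(s, p)$w[1], 2.5 * w0)
})

test_that("diffusion conserves mass and leaves uniform fields alone", {
  p <- tiny_params(D0 = 1, D1 = 1, u_res = 1000) # reservoir at 1 mM
  s <- make_state(p, u = 1e-3 * 1000)            # uniform at reservoir level
  s$u <- rep(1, p$n_cells) * s$w                 # 1 mM everywhere = u_res
  s2 <- diffusion_step(s, p, dt = 0.5)
  expect_equal(s2$u, s$u, tolerance = 1e-12)     # zero Laplacian

  # influx bookkeeping matches the content change exactly
  s <- make_state(p, u = 0)
  s2 <- diffusion_step(s, p, dt = 0.5)
  expect_equal(sum(s2$u) - sum(s$u), s2$influx, tolerance = 1e-12)
})

test_that("implicit and explicit diffusion schemes agree on a small problem", {
  p <- model_params(D0 = 0.05, D1 = 0.5, n_cells = 40, L = 4, u_res = 10,
                    k_swell = 0.05, t_end = 40, dt_out = 10, dt = 0.02)
  a <- simulate_invasion(p, scheme = "implicit")
  b <- simulate_invasion(p, scheme = "explicit")
  ref <- max(a$kymograph$intensity)
  expect_lt(max(abs(a$kymograph$intensity - b$kymograph$intensity)) / ref, 0.05)
})

test_that("free diffusion matches the constant-source erfc profile", {
  p <- model_params(D0 = 1, D1 = 1, k_bind = 0, k_swell = 0, L = 20,
                    n_cells = 400, u_res = 1, t_end = 20, dt_out = 10, dt = 0.01)
  sim <- simulate_invasion(p)
  k <- sim$kymograph
  i <- length(k$times)
  exact <- 1e-3 * erfc_num(k$positions / (2 * sqrt(k$times[i])))
  rms <- sqrt(mean((k$intensity[i, ] - exact)^2)) / 1e-3
  expect_lt(rms, 0.01)
})

test_that("simulation is deterministic and conserves both species pools", {
  p <- model_params(n_cells = 300, L = 3, t_end = 4000, dt_out = 500,
                    u_res = 4)
  a <- simulate_invasion(p)
  b <- simulate_invasion(p)
  expect_identical(a$kymograph$intensity, b$kymograph$intensity)

  s <- a$state
  # per-cell barcode conservation
  w0 <- p$L / p$n_cells
  tot <- (s$m_free + s$M_arr + s$M_sw) / (p$m_total * w0)
  expect_lt(max(abs(tot - 1)), 1e-8)
  # invader balance: domain content equals cumulative boundary influx
  content <- sum(s$u + s$M_arr + s$M_sw)
  expect_lt(abs(content - s$influx) / s$influx, 1e-6)
  # grid monotonicity: widths within [w0, g * w0] and never below w0
  expect_true(all(s$w >= w0 - 1e-12))
  expect_true(all(s$w <= 4 * w0 + 1e-12))
})

test_that("front position converges under dt halving and grid doubling", {
  base <- list(L = 7.5, u_res = 1, t_end = 2e4, dt_out = 2e3)
  p1 <- do.call(model_params, c(base, list(n_cells = 1000, dt = 1)))
  p2 <- do.call(model_params, c(base, list(n_cells = 2000, dt = 0.5)))
  pos <- function(p) {
    k <- simulate_invasion(p)$kymograph
    detect_front(k$intensity[nrow(k$intensity), ], k$positions)
  }
  x1 <- pos(p1); x2 <- pos(p2)
  expect_lt(abs(x2 - x1) / x2, 0.02)
})

test_that("radial geometry swells shells and conserves the barcode pool", {
  p <- model_params(geometry = "radial_1d", n_cells = 200, L = 3,
                    t_end = 2000, dt_out = 500, u_res = 4)
  sim <- simulate_invasion(p)
  s <- sim$state
  w0 <- p$L / p$n_cells
  expect_true(all(s$w >= w0 - 1e-12))
  expect_true(all(s$w <= 4^(1 / 3) * w0 + 1e-12)) # radial: g = f^(1/3)
  vol <- cumsum(s$w)^3 - c(0, cumsum(s$w)[-p$n_cells])^3
  tot <- s$m_free + s$M_arr + s$M_sw
  s0 <- initialize_state(p)
  expect_equal(tot, s0$m_free, tolerance = 1e-8)
  content <- sum(s$u + s$M_arr + s$M_sw)
  expect_lt(abs(content - s$influx) / s$influx, 1e-6)
})

test_that("phase_scan labels a 1x1 grid like a direct call and survives failures", {
  p <- model_params(D0 = 0.05, D1 = 0.5, n_cells = 150, L = 4, u_res = 10,
                    k_swell = 0.05, t_end = 60, dt_out = 4)
  direct <- front_analysis(simulate_invasion(p)$kymograph)$regime
  scan <- phase_scan(p, D0_values = p$D0, D1_values = p$D1,
                     k_swell_values = p$k_swell)
  expect_equal(nrow(scan), 1)
  expect_equal(scan$regime, direct)

  # invalid combination (D1 < D0) is reported, not fatal
  scan2 <- phase_scan(p, D0_values = c(0.05, 1), D1_values = 0.5,
                      k_swell_values = p$k_swell)
  bad <- scan2$D0 == 1
  expect_true(is.na(scan2$regime[bad]))
  expect_match(scan2$error[bad], "D1")
  expect_false(is.na(scan2$regime[!bad]))
})
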