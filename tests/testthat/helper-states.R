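# helpers to build small condensate states directly for unit tests

# uniform-cell state with prescribed per-cell lab-frame concentrations
make_state <- function(params, u = 0, m_free = params$m_total, M_arr = 0, M_sw = 0) {
  s <- initialize_state(params)
  n <- params$n_cells
  vol <- s$w # cartesian unit tests only
  s$u <- rep_len(u, n) * vol
  s$m_free <- rep_len(m_free, n) * vol
  s$M_arr <- rep_len(M_arr, n) * vol
  s$M_sw <- rep_len(M_sw, n) * vol
  s
}

# cheap parameter set for fast reaction/diffusion unit tests
tiny_params <- function(...) {
  model_params(n_cells = 50, L = 5, t_end = 10, dt_out = 1, ...)
}

# RK4 integrator for the per-cell reaction ODEs; independent oracle for
# the analytic reaction update
rk4_reaction <- function(u0, m0, Ma0, Ms0, k_bind, k_swell, t_end, n_steps = 20000) {
  h <- t_end / n_steps
  y <- c(u0, m0, Ma0, Ms0)
  deriv <- function(y) {
    r <- k_bind * y[1] * y[2]
    c(-r, -r, r - k_swell * y[3], k_swell * y[3])
  }
  for (i in seq_len(n_steps)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

erfc_num <- function(z) 2 * pnorm(z * sqrt(2), lower.tail = FALSE)
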