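# memoized canonical simulations shared across acceptance tests (each run
# takes tens of seconds; several criteria interrogate the same run)
.sim_cache <- new.env(parent = emptyenv())

canonical_fit <- function(regime, convention = "half_rise",
                          width_method = "half") {
  key <- paste(regime, convention, width_method, sep = "|")
  if (!exists(key, .sim_cache)) {
    sim <- canonical_sim(regime)
    assign(key, front_analysis(sim$kymograph, convention = convention,
                               width_method = width_method), .sim_cache)
  }
  get(key, .sim_cache)
}

canonical_sim <- function(regime) {
  key <- paste0("sim|", regime)
  if (!exists(key, .sim_cache)) {
    assign(key, simulate_invasion(canonical_params(regime)), .sim_cache)
  }
  get(key, .sim_cache)
}

# reservoir-concentration sweep in the ballistic-wave regime
sweep_fits <- function(u_res = c(0.5, 1, 2, 4, 8)) {
  key <- "sweep"
  if (!exists(key, .sim_cache)) {
    fits <- lapply(u_res, function(u) {
      p <- model_params(u_res = u, t_end = 6e4, dt_out = 600)
      front_analysis(simulate_invasion(p)$kymograph,
                     convention = "half_rise", width_method = "extent")
    })
    assign(key, list(u_res = u_res, fits = fits), .sim_cache)
  }
  get(key, .sim_cache)
}
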