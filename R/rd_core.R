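#' @useDynLib ballisticwave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef median mad approx quantile setNames rnorm rpois rmultinom pnorm
NULL

geometry_code <- function(geometry) match(geometry, c("cartesian_1d", "radial_1d")) - 1L

# per-cell lab-frame volumes (per unit solid angle for radial shells)
cell_volumes <- function(w, geometry) {
  if (geometry == "cartesian_1d") return(w)
  r <- cumsum(w)
  r0 <- c(0, r[-length(r)])
  (r^3 - r0^3) / 3
}

#' Initial condensate state
#'
#' Builds the uniform pre-invasion state: no invader inside the condensate,
#' free barcode at `m_total` everywhere, no bound complex, uniform material
#' cells of width `L / n_cells`. The invader reservoir enters only through
#' the boundary condition during diffusion steps.
#'
#' Species are stored as per-cell *amounts*; lab-frame concentrations are
#' amounts divided by the current cell volume (see [state_concentrations()]).
#'
#' @param params a [model_params()] object.
#' @return An object of class `condensate_state` with fields `t`, `u`,
#'   `m_free`, `M_arr`, `M_sw`, `w`, `w0`, `influx`.
#' @export
initialize_state <- function(params) {
  validate_params(params)
  n <- params$n_cells
  w0 <- params$L / n
  w <- rep(w0, n)
  vol <- cell_volumes(w, params$geometry)
  s <- list(t = 0,
            u = rep(0, n),
            m_free = params$m_total * vol,
            M_arr = rep(0, n),
            M_sw = rep(0, n),
            w = w, w0 = w0, influx = 0)
  class(s) <- "condensate_state"
  s
}

#' Lab-frame concentrations of a condensate state
#'
#' @param state a `condensate_state`.
#' @param params the matching `model_params` (needed for the geometry).
#' @return A data.frame with cell centre depth from the outer boundary
#'   (um), per-species concentrations (mM) and cell widths.
#' @export
state_concentrations <- function(state, params) {
  vol <- cell_volumes(state$w, params$geometry)
  total <- sum(state$w)
  centre <- cumsum(state$w) - state$w / 2
  data.frame(depth = total - centre,
             u = state$u / vol,
             m_free = state$m_free / vol,
             M_arr = state$M_arr / vol,
             M_sw = state$M_sw / vol,
             total_invader = (state$u + state$M_arr + state$M_sw) / vol,
             w = state$w)
}

#' @export
print.condensate_state <- function(x, ...) {
  cat(sprintf("<condensate_state> t = %g s, %d cells, domain %.3g um\n",
              x$t, length(x$u), sum(x$w)))
  cat(sprintf("  invader in domain: %.4g; cumulative influx: %.4g\n",
              sum(x$u + x$M_arr + x$M_sw), x$influx))
  invisible(x)
}

#' Local reaction kinetics over one step
#'
#' Applies, per cell, the irreversible binding `u + m_free -> M_arr`
#' (second order, diffusion-controlled, no unbinding) followed by the
#' first-order swelling conversion `M_arr -> M_sw`, each with its analytic
#' solution so no species can go negative for any `dt`. Time bookkeeping is
#' left to [simulate_invasion()]; this operation only updates the fields.
#'
#' @param state a `condensate_state`.
#' @param params a `model_params` object.
#' @param dt step length, s (> 0).
#' @return The updated `condensate_state`.
#' @export
reaction_step <- function(state, params, dt) {
  stopifnot(dt > 0)
  r <- cpp_reaction_step(state$u, state$m_free, state$M_arr, state$M_sw,
                         state$w, geometry_code(params$geometry),
                         params$k_bind * 1e-3, # 1/(M s) -> 1/(mM s)
                         params$k_swell, dt)
  state[c("u", "m_free", "M_arr", "M_sw")] <- r[c("u", "m_free", "M_arr", "M_sw")]
  state
}

#' Threshold-gated diffusivity field
#'
#' The invader diffusivity in cell `i` is `D1` when the swollen fraction
#' `phi_i = M_sw / (m_free + M_arr + M_sw)` has reached `theta`, else `D0`
#' (optionally smoothed logistically, see `switch_smooth` in
#' [model_params()]). Interface values for the flux stencil are harmonic
#' means of the adjacent cells.
#'
#' @inheritParams reaction_step
#' @return A list with `phi`, `D_cell` (length `n_cells`) and
#'   `D_interface` (length `n_cells - 1`).
#' @export
diffusivity_field <- function(state, params) {
  cpp_diffusivity(state$m_free, state$M_arr, state$M_sw,
                  params$D0, params$D1, params$theta, params$switch_smooth)
}

#' Swelling-driven geometry update
#'
#' Sets each material cell width to `w0 * (1 + (g - 1) * phi_i)` where `g`
#' is the linear expansion factor derived from `f_swell` (`g = f_swell` for
#' the 1D slab, where a volume is a length, and `g = f_swell^(1/3)` for
#' radial shells). Amount fields are untouched; widths never decrease.
#'
#' @inheritParams reaction_step
#' @return The updated `condensate_state`.
#' @export
swelling_geometry_update <- function(state, params) {
  d <- diffusivity_field(state, params)
  gf <- linear_expansion(params)
  w_new <- state$w0 * (1 + (gf - 1) * d$phi)
  state$w <- pmax(state$w, w_new)
  state
}

#' Conservative diffusion of the free invader over one step
#'
#' Finite-volume update of the free invader on the current non-uniform
#' lab-frame grid, with zero flux at the condensate centre and a fixed
#' reservoir concentration `u_res` at the outer boundary. Bound species are
#' immobile. The default backward-Euler scheme is unconditionally stable;
#' the explicit scheme sub-steps automatically to satisfy
#' `dt <= 0.4 * min(w)^2 / max(D)`.
#'
#' @inheritParams reaction_step
#' @param scheme `"implicit"` (backward Euler, default) or `"explicit"`.
#' @return The updated `condensate_state` (with `influx` accumulated).
#' @export
diffusion_step <- function(state, params, dt, scheme = c("implicit", "explicit")) {
  stopifnot(dt > 0)
  scheme <- match.arg(scheme)
  D <- diffusivity_field(state, params)$D_cell
  r <- cpp_diffusion_step(state$u, state$w, D, geometry_code(params$geometry),
                          params$u_res * 1e-3, # uM -> mM
                          dt, if (scheme == "explicit") 1L else 0L)
  state$u <- r$u
  state$influx <- state$influx + r$influx
  state
}

#' Simulate the full invasion process
#'
#' Runs the operator-split time loop (reaction, swelling, diffusion) from
#' the uniform initial state to `t_end`, and samples the total invader
#' signal `u + M_arr + M_sw` (lab-frame concentration, mM) every `dt_out`
#' on a fixed raster of depth measured from the current outer (reservoir)
#' boundary, so invasion always proceeds toward larger coordinates.
#' Identical inputs give identical outputs.
#'
#' @param params a [model_params()] object.
#' @param raster output raster of depths, um; defaults to spacing
#'   `L / n_cells` spanning the maximally swollen domain.
#' @param scheme diffusion scheme, see [diffusion_step()].
#' @return A list of class `invasion_sim` with elements `kymograph` (a
#'   [kymograph()] of the total invader signal), `state` (final
#'   `condensate_state`), and `params`.
#' @examples
#' p <- model_params(D1 = 1e-3, n_cells = 120, L = 5, t_end = 2000, dt_out = 200)
#' sim <- simulate_invasion(p)
#' dim(sim$kymograph$intensity)
#' @export
simulate_invasion <- function(params, raster = NULL, scheme = c("implicit", "explicit")) {
  validate_params(params)
  scheme <- match.arg(scheme)
  if (is.null(raster)) {
    w0 <- params$L / params$n_cells
    raster <- seq(0, params$L * linear_expansion(params), by = w0)
  }
  s0 <- initialize_state(params)
  r <- cpp_simulate(s0$u, s0$m_free, s0$M_arr, s0$M_sw, s0$w0,
                    geometry_code(params$geometry),
                    params$D0, params$D1, params$k_bind * 1e-3, params$k_swell,
                    linear_expansion(params), params$theta, params$switch_smooth,
                    params$u_res * 1e-3, params$t_end, params$dt_out,
                    default_dt(params), if (scheme == "explicit") 1L else 0L,
                    raster)
  state <- s0
  state[c("t", "u", "m_free", "M_arr", "M_sw", "w", "influx")] <-
    r[c("t", "u", "m_free", "M_arr", "M_sw", "w", "influx")]
  kym <- kymograph(r$kymograph, positions = raster, times = r$times, origin = 0)
  structure(list(kymograph = kym, state = state, params = params),
            class = "invasion_sim")
}

#' @export
print.invasion_sim <- function(x, ...) {
  cat(sprintf("<invasion_sim> %s, t_end = %g s, %d frames x %d positions\n",
              x$params$geometry, x$params$t_end,
              nrow(x$kymograph$intensity), ncol(x$kymograph$intensity)))
  invisible(x)
}

#' Phase scan over diffusivities and swelling rate
#'
#' Runs [simulate_invasion()] and [front_analysis()] for every combination
#' of the supplied `D0`, `D1` and `k_swell` values (holding all other
#' parameters at `base`), and labels each grid point with its transport
#' regime. Simulation failures are recorded per grid point without
#' aborting the scan.
#'
#' @param base a `model_params` object supplying all other parameters.
#' @param D0_values,D1_values,k_swell_values non-empty numeric vectors.
#' @param convention front-detection convention, see [detect_front()].
#' @return A data.frame with columns `D0`, `D1`, `k_swell`, `regime`
#'   (factor with the three regime labels, `NA` on failure), `alpha`,
#'   `peak_ratio`, and `error` (message or `NA`).
#' @export
phase_scan <- function(base, D0_values, D1_values, k_swell_values,
                       convention = "half_rise") {
  stopifnot(length(D0_values) > 0, length(D1_values) > 0, length(k_swell_values) > 0)
  grid <- expand.grid(D0 = D0_values, D1 = D1_values, k_swell = k_swell_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    out <- tryCatch({
      p <- base
      p$D0 <- grid$D0[i]; p$D1 <- grid$D1[i]; p$k_swell <- grid$k_swell[i]
      validate_params(p)
      fit <- front_analysis(simulate_invasion(p)$kymograph, convention = convention)
      list(regime = fit$regime, alpha = fit$alpha,
           peak_ratio = fit$median_peak_ratio, error = NA_character_)
    }, error = function(e) list(regime = NA_character_, alpha = NA_real_,
                                peak_ratio = NA_real_, error = conditionMessage(e)))
    out
  })
  grid$regime <- vapply(res, function(x) as.character(x$regime), character(1))
  grid$alpha <- vapply(res, function(x) x$alpha, numeric(1))
  grid$peak_ratio <- vapply(res, function(x) x$peak_ratio, numeric(1))
  grid$error <- vapply(res, function(x) x$error, character(1))
  grid
}
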