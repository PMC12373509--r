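# Synthetic-data generators with known ground truth. Every generator is a
# closed loop with its analysis counterpart: generate with known
# parameters, analyse, recover. These stand in for CLSM/FRAP/FLIM
# recordings; they emulate the signal models, not the optics.

erfc_ <- function(z) 2 * pnorm(z * sqrt(2), lower.tail = FALSE)

# noise descriptor: "none", list(type = "gaussian", sigma_rel =), or
# list(type = "poisson", scale = counts-per-intensity-unit)
apply_noise <- function(x, noise) {
  if (identical(noise, "none") || is.null(noise)) return(x)
  if (is.character(noise)) noise <- list(type = noise)
  switch(noise$type,
    gaussian = {
      sr <- if (is.null(noise$sigma_rel)) 0.01 else noise$sigma_rel
      x * (1 + sr * rnorm(length(x)))
    },
    poisson = {
      sc <- if (is.null(noise$scale)) 1000 else noise$scale
      rpois(length(x), pmax(x, 0) * sc) / sc
    },
    stop("unknown noise type: ", noise$type))
}

noise_label <- function(noise) {
  if (identical(noise, "none") || is.null(noise)) return("none")
  if (is.character(noise)) noise <- list(type = noise)
  if (noise$type == "gaussian")
    sprintf("gaussian(sigma_rel=%g)", if (is.null(noise$sigma_rel)) 0.01 else noise$sigma_rel)
  else sprintf("poisson(scale=%g)", if (is.null(noise$scale)) 1000 else noise$scale)
}

ground_truth <- function(generator, truth, noise, seed) {
  structure(list(generator = generator, truth = truth,
                 noise = noise_label(noise), seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (noise %s, seed %s)\n", x$generator, x$noise,
              if (is.null(x$seed)) "none" else x$seed))
  utils::str(x$truth, give.attr = FALSE)
  invisible(x)
}

#' Synthetic Fickian invasion kymograph
#'
#' Constant-source Fickian invasion of a half-line:
#' `I(x, t) = u_res * erfc(x / (2 sqrt(D t)))`, optionally with noise.
#' Front positions recovered by half-rise detection scale as `sqrt(t)`.
#'
#' @param D diffusivity, um^2/s (> 0).
#' @param u_res source intensity at `x = 0` (arbitrary units).
#' @param L domain length, um; `n_x` positions, `n_t` frames up to `t_end` s.
#' @param n_x,n_t raster sizes.
#' @param t_end final time, s.
#' @param noise noise descriptor: `"none"`, or
#'   `list(type = "gaussian", sigma_rel = )`, or
#'   `list(type = "poisson", scale = )`.
#' @param seed RNG seed used when noise is added (recorded in the ground
#'   truth; same seed, same output).
#' @return A list with `kymograph` and `ground_truth`.
#' @export
gen_fickian_kymograph <- function(D, u_res = 1, L = 20, n_x = 200, n_t = 50,
                                  t_end = 100, noise = "none", seed = 1) {
  stopifnot(D > 0)
  xs <- seq(0, L, length.out = n_x)
  ts <- seq(t_end / n_t, t_end, length.out = n_t)
  I <- outer(ts, xs, function(t, x) u_res * erfc_(x / (2 * sqrt(D * t))))
  if (!identical(noise, "none")) { set.seed(seed); I <- apply_noise(I, noise) }
  list(kymograph = kymograph(pmax(I, 0), positions = xs, times = ts, origin = 0),
       ground_truth = ground_truth("fickian_kymograph",
                                   list(D = D, u_res = u_res, exponent = 0.5),
                                   noise, seed))
}

#' Synthetic ballistic (traveling-front) kymograph
#'
#' Self-similar traveling profile emulating ballistic wave / front
#' diffusion: an invaded plateau behind the front, a Gaussian peak of
#' height `peak_ratio * plateau` and FWHM `W` centred at `x = v t`, and
#' zero intensity ahead.
#'
#' @param v front velocity, um/s (> 0).
#' @param W front width (FWHM of the peak), um (> 0).
#' @param peak_ratio peak height over plateau (>= 1; 1 gives the peakless
#'   ballistic-front profile).
#' @param plateau plateau intensity behind the front.
#' @inheritParams gen_fickian_kymograph
#' @return A list with `kymograph` and `ground_truth` (the latter records
#'   a `truncated` flag if the front exits the domain before `t_end`).
#' @export
gen_ballistic_kymograph <- function(v, W, peak_ratio = 2, plateau = 1,
                                    L = 20, n_x = 400, n_t = 50, t_end = 100,
                                    noise = "none", seed = 1) {
  stopifnot(v > 0, W > 0, peak_ratio >= 1)
  xs <- seq(0, L, length.out = n_x)
  ts <- seq(t_end / n_t, t_end, length.out = n_t)
  sg <- W / (2 * sqrt(2 * log(2)))
  I <- outer(ts, xs, function(t, x) {
    xf <- v * t
    ifelse(x <= xf,
           plateau + (peak_ratio - 1) * plateau * exp(-(x - xf)^2 / (2 * sg^2)),
           0)
  })
  if (!identical(noise, "none")) { set.seed(seed); I <- apply_noise(I, noise) }
  truncated <- v * t_end > L
  if (truncated)
    warning("front exits the domain before t_end; trace will be truncated")
  list(kymograph = kymograph(pmax(I, 0), positions = xs, times = ts, origin = 0),
       ground_truth = ground_truth("ballistic_kymograph",
                                   list(v = v, W = W, peak_ratio = peak_ratio,
                                        plateau = plateau, exponent = 1,
                                        truncated = truncated),
                                   noise, seed))
}

#' Synthetic FRAP recovery series
#'
#' Exponential recovery with an immobile fraction:
#' `I_ROI(t) = [floor + (plateau - floor) * (1 - exp(-t log(2) / t_half))]`
#' after the bleach, times a global acquisition-bleaching decay
#' `exp(-global_bleach_rate * t)` carried equally by the reference channel
#' (so double normalization removes it exactly). `t_half = Inf` encodes an
#' arrested record that never recovers.
#'
#' @param t_half ground-truth half-recovery time, s (`Inf` = arrested).
#' @param floor post-bleach intensity floor (0 <= floor < plateau).
#' @param plateau recovered plateau of the normalized curve.
#' @param T_max observation horizon, s.
#' @param dt_frame frame interval, s.
#' @param n_pre number of pre-bleach frames.
#' @param global_bleach_rate common multiplicative decay rate, 1/s.
#' @inheritParams gen_fickian_kymograph
#' @return A list with `record` (a [frap_record()]) and `ground_truth`.
#' @export
gen_frap_series <- function(t_half, floor = 0.2, plateau = 1, T_max = 6000,
                            dt_frame = 2, n_pre = 5, global_bleach_rate = 0,
                            noise = "none", seed = 1) {
  stopifnot(floor >= 0, floor < plateau)
  t_pre <- seq(0, by = dt_frame, length.out = n_pre)
  t_post <- seq(t_pre[n_pre] + dt_frame, by = dt_frame,
                length.out = ceiling(T_max / dt_frame))
  times <- c(t_pre, t_post)
  rec_t <- t_post - t_post[1]
  recov <- if (is.finite(t_half)) 1 - exp(-rec_t * log(2) / t_half) else rep(0, length(rec_t))
  I_roi <- c(rep(1, n_pre), floor + (plateau - floor) * recov)
  decay <- exp(-global_bleach_rate * times)
  I_roi <- I_roi * decay
  I_ref <- 1 * decay
  if (!identical(noise, "none")) {
    set.seed(seed)
    I_roi <- apply_noise(I_roi, noise)
    I_ref <- apply_noise(I_ref, noise)
  }
  rec <- frap_record(times, I_roi, pmax(I_ref, 1e-12), t0_index = 1, T_max = T_max)
  list(record = rec,
       ground_truth = ground_truth("frap_series",
                                   list(t_half = t_half, floor = floor,
                                        plateau = plateau,
                                        global_bleach_rate = global_bleach_rate),
                                   noise, seed))
}

#' Synthetic point-bleach stack
#'
#' Per-frame Gaussian bleach dip whose variance spreads diffusively,
#' `sigma^2(t) = sigma0^2 + 2 D t`, with amplitude decaying as
#' `sigma0 / sigma(t)` (1D conservation of the bleached deficit).
#'
#' @param D ground-truth diffusivity, um^2/s (>= 0).
#' @param sigma0 initial bleach-spot s.d., um (> 0).
#' @param n_frames number of frames; `dt` frame interval, s.
#' @param dt frame interval, s.
#' @param depth initial fractional dip depth at the bleach centre.
#' @param L half-width of the profile window, um (keep larger than the
#'   final spread `3 * sqrt(sigma0^2 + 2 D n_frames dt)` so the dip's
#'   baseline stays visible); `n_x` samples.
#' @param n_x number of profile samples.
#' @inheritParams gen_fickian_kymograph
#' @return A list with `series` (a [point_bleach_series()]) and
#'   `ground_truth`.
#' @export
gen_pointbleach_stack <- function(D, sigma0 = 1, n_frames = 20, dt = 1,
                                  depth = 0.8, L = 25, n_x = 401,
                                  noise = "none", seed = 1) {
  stopifnot(D >= 0, sigma0 > 0, depth > 0, depth <= 1)
  xs <- seq(-L, L, length.out = n_x)
  ts <- seq(0, by = dt, length.out = n_frames)
  I <- t(vapply(ts, function(t) {
    s2 <- sigma0^2 + 2 * D * t
    1 - depth * (sigma0 / sqrt(s2)) * exp(-xs^2 / (2 * s2))
  }, numeric(n_x)))
  if (!identical(noise, "none")) { set.seed(seed); I <- apply_noise(I, noise) }
  list(series = point_bleach_series(ts, I, xs),
       ground_truth = ground_truth("pointbleach_stack",
                                   list(D = D, sigma0 = sigma0, depth = depth),
                                   noise, seed))
}

#' Synthetic photon-decay histogram
#'
#' Multinomial photon sampling from a mixture of exponential decays folded
#' into the acquisition period `[0, T)` (periodic re-excitation), the
#' photon-counting analogue of Poisson noise at fixed total counts.
#' Default lifetimes 2.9 and 3.4 ns are the canonical arrested/invaded
#' anchors.
#'
#' @param tau_list component lifetimes, ns (> 0).
#' @param weights mixture weights (sum to 1).
#' @param T acquisition period, ns.
#' @param n_bins number of uniform bins.
#' @param total_counts total photons to distribute (> 0).
#' @param seed RNG seed.
#' @return A list with `decay` (a [decay_histogram()]) and `ground_truth`.
#' @export
gen_decay <- function(tau_list = c(2.9, 3.4), weights = c(0.5, 0.5), T = 25,
                      n_bins = 256, total_counts = 1e5, seed = 1) {
  stopifnot(all(tau_list > 0), length(weights) == length(tau_list))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (total_counts <= 0) stop("total_counts must be positive")
  edges <- seq(0, T, length.out = n_bins + 1)
  # folded decay: bin probability per component is
  # (exp(-a/tau) - exp(-b/tau)) / (1 - exp(-T/tau))
  p <- rep(0, n_bins)
  for (k in seq_along(tau_list)) {
    tau <- tau_list[k]
    cdf <- -expm1(-edges / tau)
    p <- p + weights[k] * diff(cdf) / (-expm1(-T / tau))
  }
  p <- p / sum(p)
  set.seed(seed)
  counts <- as.numeric(rmultinom(1, size = total_counts, prob = p))
  centres <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  list(decay = decay_histogram(centres, counts, T = T),
       ground_truth = ground_truth("decay_histogram",
                                   list(tau = tau_list, weights = weights,
                                        total_counts = total_counts),
                                   list(type = "poisson"), seed))
}
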