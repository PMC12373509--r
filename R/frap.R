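# FRAP quantification: double normalization, half-recovery time with the
# arrested-state convention, and point-bleach diffusivity from Gaussian
# spreading (sigma^2 = sigma0^2 + 2 D t).

#' FRAP record
#'
#' Intensity time series of a bleached region of interest and a reference
#' region, with the index of the first pre-bleach frame.
#'
#' @param times frame times, s.
#' @param I_ROI mean intensity of the bleached region per frame.
#' @param I_ref mean intensity of the reference region per frame (> 0).
#' @param t0_index index of the first pre-bleach frame (its intensities
#'   anchor the normalization).
#' @param T_max observation horizon, s; an absent recovery within `T_max`
#'   is reported with the arrested-state convention `t_half = T_max`.
#' @return An object of class `frap_record`.
#' @export
frap_record <- function(times, I_ROI, I_ref, t0_index = 1, T_max = 6000) {
  stopifnot(length(times) == length(I_ROI), length(times) == length(I_ref),
            all(diff(times) > 0), t0_index >= 1, t0_index <= length(times),
            T_max > 0)
  if (any(I_ref <= 0)) stop("reference intensity must be positive at all frames")
  structure(list(times = times, I_ROI = I_ROI, I_ref = I_ref,
                 t0_index = as.integer(t0_index), T_max = T_max),
            class = "frap_record")
}

#' FRAP double normalization
#'
#' Normalizes the bleached-region recovery by the reference region,
#' removing acquisition photobleaching:
#' `I_norm(t) = (I_ROI(t) / I_ROI(t0)) * (I_ref(t0) / I_ref(t))`,
#' where `t0` is the first pre-bleach frame. The result is exactly
#' invariant under any common multiplicative drift of both channels and
#' equals 1 at `t0` by construction.
#'
#' @param rec a [frap_record()].
#' @return The record with an `I_norm` field added.
#' @export
double_normalize <- function(rec) {
  stopifnot(inherits(rec, "frap_record"))
  i0 <- rec$t0_index
  if (rec$I_ROI[i0] <= 0) stop("pre-bleach ROI intensity must be positive")
  rec$I_norm <- (rec$I_ROI / rec$I_ROI[i0]) * (rec$I_ref[i0] / rec$I_ref)
  rec
}

#' Half-recovery time of a FRAP curve
#'
#' The half-recovery time is the first time (linearly interpolated between
#' frames) at which the normalized curve reaches the level halfway between
#' the post-bleach floor (curve minimum) and the final plateau (median of
#' the last 10% of frames), measured from the bleach frame. Records that
#' never recover within `T_max` -- no crossing, or a recovery amplitude
#' below `arrest_frac` of the bleached depth -- are reported as arrested
#' with `t_half = T_max` (the 1/6000 s^-1 convention for 6000-s
#' observations).
#'
#' @param x a [frap_record()] (double-normalized automatically) or a
#'   numeric normalized curve.
#' @param times frame times, s (required when `x` is a bare curve).
#' @param T_max observation horizon, s (taken from the record if present).
#' @param arrest_frac minimum recovered fraction of the bleached depth for
#'   the record to count as recovering at all.
#' @return A list with `t_half` (s) and `arrested` (logical).
#' @examples
#' t <- seq(0, 300, 2)
#' curve <- 1 - 0.8 * exp(-t * log(2) / 30)
#' half_recovery_time(curve, times = t)$t_half  # ~30 s
#' @export
half_recovery_time <- function(x, times = NULL, T_max = NULL, arrest_frac = 0.05) {
  if (inherits(x, "frap_record")) {
    if (is.null(x$I_norm)) x <- double_normalize(x)
    curve <- x$I_norm
    times <- x$times
    if (is.null(T_max)) T_max <- x$T_max
    pre_level <- curve[x$t0_index]
  } else {
    curve <- as.numeric(x)
    if (is.null(times)) stop("times must be supplied with a bare curve")
    if (is.null(T_max)) T_max <- 6000
    pre_level <- max(curve)
  }
  stopifnot(length(curve) == length(times))
  i_min <- which.min(curve)
  if (i_min == length(curve)) {
    # monotone decay: nothing after the bleach
    return(list(t_half = T_max, arrested = TRUE))
  }
  floor_ <- curve[i_min]
  t_bleach <- times[i_min]
  n10 <- max(1, round(0.1 * length(curve)))
  plateau <- median(utils::tail(curve, n10))
  depth <- pre_level - floor_
  if (depth <= 0) depth <- max(abs(curve), 1e-300)
  if ((plateau - floor_) < arrest_frac * depth) {
    return(list(t_half = T_max, arrested = TRUE))
  }
  target <- (floor_ + plateau) / 2
  post <- i_min:length(curve)
  cv <- curve[post]; tv <- times[post]
  above <- which(cv >= target)
  if (!length(above)) return(list(t_half = T_max, arrested = TRUE))
  j <- above[1]
  if (j == 1) {
    t_cross <- tv[1]
  } else {
    t_cross <- tv[j - 1] + (target - cv[j - 1]) * (tv[j] - tv[j - 1]) / (cv[j] - cv[j - 1])
  }
  t_half <- t_cross - t_bleach
  if (t_half > T_max) return(list(t_half = T_max, arrested = TRUE))
  list(t_half = t_half, arrested = FALSE)
}

#' Gaussian variance of a point-bleach line profile
#'
#' Nonlinear least-squares fit of `A * exp(-(x - mu)^2 / (2 sigma^2)) + c`
#' (dip or peak; `A` may be negative) returning the squared standard
#' deviation `sigma^2`.
#'
#' @param profile intensity values.
#' @param positions matching coordinates, um.
#' @return `sigma^2` (um^2), with the fitted parameters as attribute
#'   `"fit_pars"`.
#' @export
gaussian_sigma2 <- function(profile, positions) {
  profile <- unname(as.numeric(profile))
  positions <- unname(as.numeric(positions))
  stopifnot(length(profile) == length(positions), length(profile) >= 5)
  scale <- max(abs(profile), 1e-300)
  if (diff(range(profile)) <= 1e-10 * scale)
    stop("flat profile: no Gaussian feature to fit")
  m <- max(3, round(length(profile) / 10))
  c0 <- median(c(utils::head(profile, m), utils::tail(profile, m))) # edges: baseline
  dev <- profile - c0
  i0 <- which.max(abs(dev))
  A0 <- dev[i0]
  mu0 <- positions[i0]
  wts <- abs(dev)
  s0 <- sqrt(sum(wts * (positions - mu0)^2) / sum(wts))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(positions)) / 10
  df <- data.frame(x = positions, y = profile)
  # perturbed restarts: a start too close to the optimum can present the
  # Levenberg-Marquardt solver with a numerically singular gradient
  starts <- list(c(1, 0, 1), c(1.3, 0.25, 1), c(0.7, -0.25, 1.3), c(1.5, 0.5, 0.8))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sg^2)) + c0f,
                        data = df,
                        start = list(A = A0 * st[3], mu = mu0 + st[2] * s0,
                                     sg = s0 * st[1], c0f = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("Gaussian fit did not converge")
  pars <- coef(fit)
  rss <- sum(stats::resid(fit)^2)
  if (!is.finite(pars[["sg"]]))
    stop(sprintf("Gaussian fit did not converge (residual sum of squares %.3g)", rss))
  structure(unname(pars[["sg"]]^2),
            fit_pars = c(A = unname(pars[["A"]]), mu = unname(pars[["mu"]]),
                         sigma = abs(unname(pars[["sg"]])), c = unname(pars[["c0f"]]),
                         rss = rss))
}

#' Point-bleach profile series
#'
#' @param times frame times, s.
#' @param profiles matrix `[n_frames x n_positions]` of intensity profiles
#'   through the bleached spot.
#' @param positions profile coordinates, um.
#' @return An object of class `point_bleach_series`.
#' @export
point_bleach_series <- function(times, profiles, positions) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == length(times), ncol(profiles) == length(positions),
            all(diff(times) > 0))
  structure(list(times = times, profiles = profiles, positions = positions),
            class = "point_bleach_series")
}

#' Diffusion coefficient from point-bleach Gaussian spreading
#'
#' Fits each frame's profile with [gaussian_sigma2()] and estimates the
#' diffusion coefficient from the linear growth of the variance,
#' `sigma^2(t) = sigma0^2 + 2 D t`, i.e. `D` is half the slope of
#' `sigma^2` versus time.
#'
#' @param series a [point_bleach_series()], or a list/data.frame with
#'   `times` and precomputed `sigma2`.
#' @return A list with `D` (um^2/s), `se`, `sigma2`, `times`, `n_valid`.
#' @export
fit_diffusion_coefficient <- function(series) {
  if (inherits(series, "point_bleach_series")) {
    sigma2 <- vapply(seq_along(series$times), function(i) {
      tryCatch(as.numeric(gaussian_sigma2(series$profiles[i, ], series$positions)),
               error = function(e) NA_real_)
    }, numeric(1))
    times <- series$times
  } else {
    sigma2 <- series$sigma2
    times <- series$times
  }
  ok <- is.finite(sigma2)
  if (sum(ok) < 3) stop("need at least 3 frames with a valid sigma^2")
  fit <- lm(sigma2[ok] ~ times[ok])
  list(D = unname(coef(fit)[2]) / 2,
       se = unname(suppressWarnings(summary(fit))$coefficients[2, 2]) / 2,
       sigma2 = sigma2, times = times, n_valid = sum(ok))
}
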