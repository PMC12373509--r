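# Front kinetics: extract position, width, velocity, peak ratio and
# scaling exponent from kymographs and classify the transport regime.
# Convention used throughout: the invaded region sits at SMALL coordinates
# ("behind" the front) and the pristine region at LARGE coordinates
# ("ahead"); fronts advance toward +x.

# all interpolated positions where the piecewise-linear profile crosses
# `level`, in ascending position order
level_crossings <- function(profile, positions, level) {
  s <- profile - level
  idx <- which(s[-length(s)] * s[-1] < 0 | (s[-length(s)] != 0 & s[-1] == 0))
  if (!length(idx)) return(numeric(0))
  vapply(idx, function(i) {
    positions[i] + (level - profile[i]) *
      (positions[i + 1] - positions[i]) / (profile[i + 1] - profile[i])
  }, numeric(1))
}

#' Detect the front position in a single intensity profile
#'
#' Two conventions: `"peak"` returns the position of the intensity maximum
#' (suited to the wave regime, which carries a high-intensity peak at the
#' front); `"half_rise"` returns the outermost (largest-coordinate)
#' crossing of the level halfway between the profile maximum and minimum.
#' Ties break toward the larger coordinate.
#'
#' @param profile numeric intensity profile (length >= 5).
#' @param positions matching strictly increasing coordinates, um.
#' @param convention `"half_rise"` (default) or `"peak"`.
#' @param noise_floor profiles whose total excursion `max - min` does not
#'   exceed this are considered flat (no front); default
#'   `1e-8 * max(abs(profile))`.
#' @return The front coordinate (um), or `NA_real_` if no front is found.
#' @examples
#' x <- seq(0, 10, 0.1)
#' detect_front(ifelse(x < 5, 1, 0), x)           # step at 5
#' detect_front(exp(-(x - 3)^2) + 1, x, "peak")   # bump at 3
#' @export
detect_front <- function(profile, positions,
                         convention = c("half_rise", "peak"),
                         noise_floor = NULL) {
  convention <- match.arg(convention)
  stopifnot(length(profile) >= 5, length(profile) == length(positions),
            all(diff(positions) > 0))
  if (is.null(noise_floor)) noise_floor <- 1e-8 * max(abs(profile), 1e-300)
  if (diff(range(profile)) <= noise_floor) return(NA_real_)
  if (convention == "peak") {
    return(positions[max(which(profile == max(profile)))])
  }
  level <- (max(profile) + min(profile)) / 2
  cr <- level_crossings(profile, positions, level)
  if (!length(cr)) return(NA_real_)
  max(cr)
}

# robust plateau level immediately behind the front peak: median over the
# `frac` share of positions just inside the invaded region, after stepping
# past the peak's own shoulder
plateau_behind <- function(profile, positions, k_peak, frac = 0.1) {
  behind <- seq_len(k_peak - 1)
  if (length(behind) < 3) stop("no plateau behind the front (front at boundary)")
  hi <- profile[k_peak]
  # pass 1: coarse level from everything behind; pass 2: step past the
  # peak's skirt (first point, moving inward, below a 25% excess over the
  # coarse level) before taking the plateau window
  m1 <- median(profile[behind])
  bound <- m1 + 0.25 * (hi - m1)
  inner <- behind[profile[behind] < bound]
  if (length(inner) < 3) inner <- behind
  j <- max(inner)
  j <- max(1L, j - 2L * (k_peak - j)) # two more skirt half-widths clear
  n10 <- max(3, round(frac * length(profile)))
  sel <- seq(max(1, j - n10 + 1), j)
  median(profile[sel])
}

#' Front width of a single profile
#'
#' Two width measures are available. `method = "half"` (default): when the
#' profile carries a peak (maximum exceeding the plateau behind it by the
#' factor `peak_factor`), the width is the full width at half maximum of
#' the peak, measured between the half-level crossings nearest the peak on
#' either side (each side referenced to its own baseline: the plateau
#' behind, the minimum ahead); without a peak, it is the distance between
#' the outermost 16% and 84% rise levels of the profile excursion.
#' `method = "extent"`: the full width of the high-intensity front band,
#' from the leading half-rise to the trailing position where the signal
#' has relaxed to within 16% of the invaded plateau `I_0` behind the
#' front. The half-maximum width tracks the peak's internal shape, whose
#' amplitude varies with conditions and sharpens with grid resolution; the
#' extent width is insensitive to the peak amplitude and is the measure to
#' use when comparing front widths across conditions (it requires a
#' positive plateau, i.e. an invaded region behind the front).
#'
#' @inheritParams detect_front
#' @param peak_factor multiplicative excess over the plateau behind that
#'   qualifies as a peak (default 1.2).
#' @param method `"half"` (FWHM / 16-84 rise) or `"extent"` (band width).
#' @return Front width W, um.
#' @examples
#' x <- seq(-10, 10, 0.01)
#' front_width(exp(-x^2 / (2 * 4)), x)  # FWHM of a Gaussian, 2.3548 * 2
#' @export
front_width <- function(profile, positions,
                        convention = c("half_rise", "peak"),
                        noise_floor = NULL, peak_factor = 1.2,
                        method = c("half", "extent")) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  p <- detect_front(profile, positions, convention, noise_floor)
  if (is.na(p)) stop("no front detected; width undefined")
  k <- max(which(profile == max(profile)))
  lo <- min(profile)
  hi <- max(profile)
  plateau <- tryCatch(plateau_behind(profile, positions, k), error = function(e) NA_real_)
  has_peak <- is.finite(plateau) && plateau >= 0 && hi >= peak_factor * plateau &&
    k > 1 && k < length(profile)
  if (method == "extent") {
    if (!is.finite(plateau) || plateau <= 0)
      stop("extent width needs a positive invaded plateau behind the front")
    ahead <- if (k < length(profile)) min(profile[(k + 1):length(profile)]) else lo
    cr_r <- level_crossings(profile, positions, (hi + ahead) / 2)
    lead <- cr_r[cr_r > positions[k]]
    if (!length(lead)) stop("front feature truncated at the profile boundary")
    # trailing edge: first position inward of the peak where the signal has
    # relaxed back to within 16% of the plateau level
    cr_t <- level_crossings(profile, positions, 1.16 * plateau)
    trail <- cr_t[cr_t < positions[k]]
    trail <- if (length(trail)) max(trail) else positions[1]
    return(min(lead) - trail)
  }
  if (has_peak) {
    # half level per side, referenced to that side's baseline (the minimum
    # behind, the minimum ahead); both reduce to the classic FWHM for a
    # peak on a flat background
    ahead <- if (k < length(profile)) min(profile[(k + 1):length(profile)]) else lo
    behind_min <- min(profile[seq_len(k - 1)])
    cr_l <- level_crossings(profile, positions, (hi + behind_min) / 2)
    cr_r <- level_crossings(profile, positions, (hi + ahead) / 2)
    left <- cr_l[cr_l < positions[k]]
    right <- cr_r[cr_r > positions[k]]
    if (!length(left) || !length(right))
      stop("front feature truncated at the profile boundary")
    return(min(right) - max(left))
  }
  l16 <- lo + 0.16 * (hi - lo)
  l84 <- lo + 0.84 * (hi - lo)
  c16 <- level_crossings(profile, positions, l16)
  c84 <- level_crossings(profile, positions, l84)
  if (!length(c16) || !length(c84)) stop("rise levels not crossed; width undefined")
  abs(max(c16) - max(c84))
}

#' Peak ratio I_p / I_0 of a single profile
#'
#' Maximum intensity in the front region divided by the plateau intensity
#' behind it (median of the positions immediately behind the front,
#' robust to the peak itself). Equals 1 for a flat invaded plateau without
#' a peak; the ballistic-wave regime gives values > 1.
#'
#' @inheritParams detect_front
#' @param frac share of positions used for the plateau estimate.
#' @return The dimensionless ratio I_p / I_0.
#' @export
peak_ratio <- function(profile, positions = seq_along(profile), frac = 0.1) {
  k <- max(which(profile == max(profile)))
  plateau <- plateau_behind(profile, positions, k, frac)
  if (!is.finite(plateau) || plateau <= 0) stop("no positive plateau behind the front")
  max(profile) / plateau
}

#' Per-frame front trace of a kymograph
#'
#' Applies [detect_front()], [front_width()] and [peak_ratio()] to every
#' frame; frames without a detectable front are excluded.
#'
#' @param kym a [kymograph()].
#' @inheritParams detect_front
#' @param width_method width measure forwarded to [front_width()].
#' @return A data.frame of class `front_trace` with columns `t`, `X_front`
#'   (displacement from the kymograph origin, um), `W` (um) and
#'   `I_p_over_I0` (the latter two `NA` where undefined), and attributes
#'   `convention` and `origin`.
#' @export
front_trace <- function(kym, convention = c("half_rise", "peak"),
                        noise_floor = NULL, width_method = c("half", "extent")) {
  width_method <- match.arg(width_method)
  stopifnot(inherits(kym, "kymograph"))
  convention <- match.arg(convention)
  if (length(kym$times) < 5) stop("need at least 5 frames")
  rows <- lapply(seq_along(kym$times), function(i) {
    prof <- kym$intensity[i, ]
    p <- detect_front(prof, kym$positions, convention, noise_floor)
    if (is.na(p)) return(NULL)
    W <- tryCatch(front_width(prof, kym$positions, convention, noise_floor,
                              method = width_method),
                  error = function(e) NA_real_)
    r <- tryCatch(peak_ratio(prof, kym$positions), error = function(e) NA_real_)
    data.frame(t = kym$times[i], X_front = p - kym$origin, W = W, I_p_over_I0 = r)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 3) stop("insufficient data: fewer than 3 frames with a detectable front")
  out <- do.call(rbind, rows)
  structure(out, class = c("front_trace", "data.frame"),
            convention = convention, origin = kym$origin)
}

# default fit window: drop the first 10% (front establishment) and the
# final 20% (late-stage interference) of the time range
default_window <- function(times) {
  r <- range(times)
  c(r[1] + 0.1 * diff(r), r[1] + 0.8 * diff(r))
}

#' Fit the front-displacement scaling exponent
#'
#' Least-squares slope of `log(X_front)` versus `log(t)` inside the fit
#' window. Ballistic transport gives an exponent of 1, Fickian transport
#' 0.5.
#'
#' @param trace a [front_trace()] (or data.frame with `t`, `X_front`).
#' @param window `c(t_lo, t_hi)`, s; the default drops the first 10% and
#'   final 20% of the time range.
#' @return A list with `alpha`, `se`, `window`, `n`.
#' @export
fit_scaling_exponent <- function(trace, window = NULL) {
  if (is.null(window)) window <- default_window(trace$t)
  sel <- trace$t >= window[1] & trace$t <= window[2]
  tt <- trace$t[sel]; xx <- trace$X_front[sel]
  if (any(tt <= 0) || any(xx <= 0))
    stop("non-positive times or displacements inside the fit window")
  if (length(tt) < 5) stop("need at least 5 points inside the fit window")
  fit <- lm(log(xx) ~ log(tt))
  list(alpha = unname(coef(fit)[2]),
       se = unname(suppressWarnings(summary(fit))$coefficients[2, 2]),
       window = window, n = length(tt))
}

#' Fit the front velocity
#'
#' Linear least squares of `X_front` versus `t` inside the fit window.
#'
#' @inheritParams fit_scaling_exponent
#' @return A list with `v` (um/s), `se`, `intercept`, `window`, `n`.
#' @export
fit_velocity <- function(trace, window = NULL) {
  if (is.null(window)) window <- default_window(trace$t)
  sel <- trace$t >= window[1] & trace$t <= window[2]
  tt <- trace$t[sel]; xx <- trace$X_front[sel]
  if (length(tt) < 3) stop("need at least 3 points inside the fit window")
  fit <- lm(xx ~ tt)
  list(v = unname(coef(fit)[2]),
       se = unname(suppressWarnings(summary(fit))$coefficients[2, 2]),
       intercept = unname(coef(fit)[1]),
       window = window, n = length(tt))
}

#' Log-log power-law fit
#'
#' Fits `y = prefactor * x^exponent` by least squares in log-log space;
#' used for velocity versus invader concentration and velocity versus
#' front width.
#'
#' @param xs,ys positive numeric vectors (length >= 3).
#' @return A list with `exponent`, `prefactor`, `r_squared`, `se`.
#' @examples
#' scaling_law_fit(1:10, 3 * (1:10)^2)$exponent
#' @export
scaling_law_fit <- function(xs, ys) {
  if (length(xs) < 3 || length(xs) != length(ys)) stop("need >= 3 (x, y) pairs")
  if (any(xs <= 0) || any(ys <= 0)) stop("power-law fit needs positive inputs")
  fit <- lm(log(ys) ~ log(xs))
  list(exponent = unname(coef(fit)[2]),
       prefactor = exp(unname(coef(fit)[1])),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       se = unname(suppressWarnings(summary(fit))$coefficients[2, 2]))
}

#' Classify the transport regime
#'
#' Fickian when the displacement exponent is below `alpha_fickian`;
#' otherwise ballistic wave if the median peak ratio reaches `wave_ratio`,
#' else ballistic front.
#'
#' @param trace a [front_analysis()] result, or `NULL` when `alpha` and
#'   `peak_ratio` are given directly.
#' @param alpha fitted displacement exponent.
#' @param peak_ratio median I_p / I_0 over the trace.
#' @param alpha_fickian,wave_ratio classification thresholds.
#' @return One of `"fickian"`, `"ballistic_front"`, `"ballistic_wave"`.
#' @export
classify_regime <- function(trace = NULL, alpha = NULL, peak_ratio = NULL,
                            alpha_fickian = 0.7, wave_ratio = 1.2) {
  if (!is.null(trace)) {
    if (!inherits(trace, "front_fit") || is.null(trace$alpha))
      stop("trace must be a front_analysis() result with a fitted exponent")
    alpha <- trace$alpha
    peak_ratio <- trace$median_peak_ratio
  }
  if (is.null(alpha) || !is.finite(alpha)) stop("alpha must be a finite number")
  if (alpha < alpha_fickian) return("fickian")
  if (is.finite(peak_ratio) && peak_ratio >= wave_ratio) return("ballistic_wave")
  "ballistic_front"
}

#' Full front analysis of a kymograph
#'
#' Convenience wrapper: builds the [front_trace()], fits velocity and
#' scaling exponent over the window, summarizes the peak ratio and
#' classifies the regime.
#'
#' @inheritParams front_trace
#' @inheritParams fit_scaling_exponent
#' @inheritParams front_trace
#' @param alpha_fickian,wave_ratio thresholds for [classify_regime()].
#' @return An object of class `front_fit`: list with `trace`, `v`, `v_se`,
#'   `alpha`, `alpha_se`, `median_peak_ratio`, `median_width`, `regime`,
#'   `fit_window`, `convention`.
#' @export
front_analysis <- function(kym, convention = c("half_rise", "peak"),
                           window = NULL, noise_floor = NULL,
                           alpha_fickian = 0.7, wave_ratio = 1.2,
                           width_method = c("half", "extent")) {
  convention <- match.arg(convention)
  width_method <- match.arg(width_method)
  trace <- front_trace(kym, convention, noise_floor, width_method)
  vfit <- fit_velocity(trace, window)
  afit <- fit_scaling_exponent(trace, window)
  sel <- trace$t >= afit$window[1] & trace$t <= afit$window[2]
  mpr <- median(trace$I_p_over_I0[sel], na.rm = TRUE)
  mw <- median(trace$W[sel], na.rm = TRUE)
  out <- list(trace = trace, v = vfit$v, v_se = vfit$se,
              alpha = afit$alpha, alpha_se = afit$se,
              median_peak_ratio = mpr, median_width = mw,
              fit_window = afit$window, convention = convention)
  class(out) <- "front_fit"
  out$regime <- classify_regime(out, alpha_fickian = alpha_fickian,
                                wave_ratio = wave_ratio)
  out
}

#' @export
print.front_fit <- function(x, ...) {
  cat(sprintf("<front_fit> regime = %s\n", x$regime))
  cat(sprintf("  v = %.4g +/- %.2g um/s, alpha = %.3f +/- %.3f\n",
              x$v, x$v_se, x$alpha, x$alpha_se))
  cat(sprintf("  median I_p/I_0 = %.3f, median W = %.4g um, window [%g, %g] s\n",
              x$median_peak_ratio, x$median_width, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}
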