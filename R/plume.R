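#' Specification of a naturalistic plume pair
#'
#' Describes a pair of odorant concentration time series with the
#' statistics of turbulent plumes measured downwind of a source at zero
#' crosswind distance: whiff (odor-on) and blank (odor-off) durations follow
#' a truncated power law with exponent -3/2, and the concentration during a
#' whiff follows a fitted piecewise distribution of the normalized
#' concentration C / <C>.  A Gaussian copula couples the two channels'
#' draws so that their whiff durations, blank durations and concentrations
#' carry a controllable correlation, emulating a shared source
#' (correlation near 1) versus separate sources (near 0).
#'
#' @param rho_target Intended copula correlation in [0, 1].
#' @param t_total Series duration in seconds (200 s for full runs, a few s
#'   for demos).
#' @param whiff_min,whiff_max Truncation bounds for whiff durations (s).
#' @param blank_min,blank_max Bounds for blank durations (s); same power
#'   law as whiffs.
#' @param exponent Power-law exponent for both duration distributions
#'   (< -1; default -3/2).
#' @param a1,b1 Parameters of the fitted concentration distribution.
#' @param mean_conc Target mean whiff concentration (v/v proxy units).
#' @param dt Sampling step of the generated waveform (ms).
#' @return A list of class \code{"plume_spec"}.
#' @export
plume_spec <- function(rho_target = 0, t_total = 200, whiff_min = 0.03,
                       whiff_max = 50, blank_min = 0.03,
                       blank_max = whiff_max, exponent = -1.5, a1 = 0.22,
                       b1 = 0.26, mean_conc = 1.5e-3, dt = 0.1) {
  if (rho_target < 0 || rho_target > 1) {
    stop("rho_target must lie in [0, 1]", call. = FALSE)
  }
  if (!(whiff_min > 0 && whiff_min < whiff_max)) {
    stop("need 0 < whiff_min < whiff_max", call. = FALSE)
  }
  if (!(blank_min > 0 && blank_min < blank_max)) {
    stop("need 0 < blank_min < blank_max", call. = FALSE)
  }
  if (exponent >= -1) stop("exponent must be < -1", call. = FALSE)
  structure(list(rho_target = rho_target, t_total = t_total,
                 whiff_min = whiff_min, whiff_max = whiff_max,
                 blank_min = blank_min, blank_max = blank_max,
                 exponent = exponent, a1 = a1, b1 = b1,
                 mean_conc = mean_conc, dt = dt),
            class = "plume_spec")
}

#' Correlated uniform pairs via a Gaussian copula
#'
#' Draws \code{n} pairs of standard bivariate Gaussians with correlation
#' \code{rho} and maps each coordinate through the standard normal CDF,
#' yielding pairs of uniforms on (0, 1) with the prescribed Gaussian-copula
#' dependence.
#'
#' @param rho Correlation in [0, 1].
#' @param n Number of pairs.
#' @return An \code{n x 2} matrix of uniforms.
#' @export
sample_correlated_uniform_pairs <- function(rho, n) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(stats::pnorm(z1), stats::pnorm(z2))
}

#' Inverse CDF of the truncated power-law duration distribution
#'
#' Quantile function of the density proportional to t^exponent on
#' [t_min, t_max].  For the default exponent -3/2 this reduces to
#' t = (t_min^(-1/2) - u (t_min^(-1/2) - t_max^(-1/2)))^(-2).
#'
#' @param u Uniform variate(s) in [0, 1].
#' @param t_min,t_max Truncation bounds, 0 < t_min < t_max.
#' @param exponent Power-law exponent (< -1).
#' @return Duration(s) in the units of \code{t_min}/\code{t_max}.
#' @examples
#' inv_powerlaw_duration(0, 0.03, 50)    # t_min
#' inv_powerlaw_duration(0.5, 0.03, 50)  # ~0.114 s
#' @export
inv_powerlaw_duration <- function(u, t_min, t_max, exponent = -1.5) {
  if (!(t_min > 0 && t_min < t_max)) {
    stop("need 0 < t_min < t_max", call. = FALSE)
  }
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]", call. = FALSE)
  e1 <- exponent + 1    # < 0
  (t_min^e1 + u * (t_max^e1 - t_min^e1))^(1 / e1)
}

#' Inverse CDF of the normalized whiff concentration
#'
#' The normalized concentration x = C / <C> has CDF (5/3) x on
#' 0 <= x <= 0.3 and 1 - 10^-(a1 + b1 x) above; its inverse is
#' x = (3/5) u for u <= 0.5 and x = (-log10(1 - u) - a1) / b1 otherwise.
#' The two branches disagree by about 0.3\% in probability at x = 0.3; the
#' piecewise form is applied verbatim, so the quantile function has a small
#' jump at u = 0.5.
#'
#' @param u Uniform variate(s) in [0, 1).
#' @param a1,b1 Distribution parameters.
#' @return Normalized concentration(s), >= 0.
#' @examples
#' inv_concentration(0.4)  # 0.24
#' inv_concentration(0.9)  # 3.0
#' @export
inv_concentration <- function(u, a1 = 0.22, b1 = 0.26) {
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)", call. = FALSE)
  ifelse(u <= 0.5, 0.6 * u, (-log10(1 - u) - a1) / b1)
}

# analytic mean of the normalized concentration distribution; used to scale
# whiff concentrations so that their expectation equals mean_conc
mean_norm_conc <- function(a1 = 0.22, b1 = 0.26) {
  lower <- 0.6 * 0.5^2 / 2              # int_0^0.5 0.6 u du
  # upper branch: x(v) = (-log10(v) - a1)/b1 with v = 1 - u on (0, 0.5)
  int_neglog <- 0.5 - 0.5 * log(0.5)    # int_0^0.5 -ln(v) dv
  upper <- (int_neglog / log(10) - a1 * 0.5) / b1
  lower + upper
}

#' Generate a correlated pair of plume concentration time series
#'
#' Builds each channel as an alternating sequence of blanks (zero
#' concentration) and rectangular whiffs (constant concentration for the
#' whole whiff, one draw per whiff).  The three draw streams -- whiff
#' duration, blank duration and whiff concentration -- are sampled pairwise
#' across the channels through a shared Gaussian copula with correlation
#' \code{rho_target}; alignment of whiff onsets then emerges from the
#' cumulative durations.  At \code{rho_target = 1} the two channels are
#' identical.
#'
#' @param spec A \code{"plume_spec"}.
#' @return A \code{"stimulus_waveform"} spanning \code{spec$t_total}
#'   seconds at \code{spec$dt} ms resolution.
#' @export
generate_plume_pair <- function(spec) {
  stopifnot(inherits(spec, "plume_spec"))
  t_total_ms <- spec$t_total * 1000
  n_samp <- floor(t_total_ms / spec$dt) + 1
  conc <- matrix(0, n_samp, 2)
  # cursor per channel, in samples
  pos <- c(1, 1)
  mean_x <- mean_norm_conc(spec$a1, spec$b1)
  repeat {
    ub <- sample_correlated_uniform_pairs(spec$rho_target, 1)
    uw <- sample_correlated_uniform_pairs(spec$rho_target, 1)
    uc <- sample_correlated_uniform_pairs(spec$rho_target, 1)
    blank <- inv_powerlaw_duration(ub, spec$blank_min, spec$blank_max,
                                   spec$exponent) * 1000
    whiff <- inv_powerlaw_duration(uw, spec$whiff_min, spec$whiff_max,
                                   spec$exponent) * 1000
    cval <- inv_concentration(pmin(uc, 1 - 1e-12), spec$a1, spec$b1) *
      spec$mean_conc / mean_x
    for (ch in 1:2) {
      if (pos[ch] > n_samp) next
      b_samp <- round(blank[ch] / spec$dt)
      w_samp <- round(whiff[ch] / spec$dt)
      from <- min(pos[ch] + b_samp, n_samp + 1)
      to <- min(pos[ch] + b_samp + w_samp - 1, n_samp)
      if (from <= to) conc[from:to, ch] <- cval[ch]
      pos[ch] <- pos[ch] + b_samp + w_samp
    }
    if (all(pos > n_samp)) break
  }
  t <- seq(0, by = spec$dt, length.out = n_samp)
  stimulus_waveform(t, conc[, 1], conc[, 2],
                    meta = c(list(kind = "plume"), unclass(spec)))
}

#' Realized statistics of a plume pair
#'
#' @param w A \code{"stimulus_waveform"} (typically from
#'   \code{\link{generate_plume_pair}}).
#' @param t_min,t_max Truncation bounds (s) assumed for the whiff-duration
#'   power law when estimating its exponent; defaults are taken from the
#'   waveform's metadata when present.
#' @return A list of class \code{"plume_stats"}: \code{intermittency} (per
#'   channel, fraction of samples with nonzero concentration),
#'   \code{mean_conc} (per channel, time average), \code{rho_realized}
#'   (linear correlation of the two channels) and \code{exponent_hat}
#'   (truncation-aware maximum-likelihood power-law exponent of the pooled
#'   whiff durations, excluding whiffs cut by the series boundaries;
#'   \code{NA} if fewer than 10 whiffs).
#' @export
measure_plume_stats <- function(w, t_min = NULL, t_max = NULL) {
  stopifnot(inherits(w, "stimulus_waveform"))
  if (all(w$conc_a == 0) && all(w$conc_b == 0)) {
    stop("all-zero waveform: correlation undefined", call. = FALSE)
  }
  if (is.null(t_min)) t_min <- w$meta$whiff_min %||% NULL
  if (is.null(t_max)) t_max <- w$meta$whiff_max %||% NULL
  inter <- c(a = mean(w$conc_a > 0), b = mean(w$conc_b > 0))
  mc <- c(a = mean(w$conc_a), b = mean(w$conc_b))
  rho <- if (stats::sd(w$conc_a) == 0 || stats::sd(w$conc_b) == 0) {
    NA_real_
  } else {
    stats::cor(w$conc_a, w$conc_b)
  }
  dur <- c(whiff_durations(w$conc_a, w$dt), whiff_durations(w$conc_b, w$dt)) / 1000
  exp_hat <- NA_real_
  if (length(dur) >= 10 && !is.null(t_min) && !is.null(t_max)) {
    exp_hat <- fit_powerlaw_exponent(dur, t_min, t_max)
  }
  structure(list(intermittency = inter, mean_conc = mc, rho_realized = rho,
                 exponent_hat = exp_hat, n_whiffs = length(dur)),
            class = "plume_stats")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# durations (ms) of interior runs of nonzero concentration; runs touching
# either end of the series are dropped as boundary-truncated
whiff_durations <- function(conc, dt) {
  r <- rle(conc > 0)
  on <- which(r$values)
  if (length(on) == 0) return(numeric(0))
  if (length(on) > 0 && on[1] == 1) on <- on[-1]
  if (length(on) > 0 && on[length(on)] == length(r$values)) {
    on <- on[-length(on)]
  }
  r$lengths[on] * dt
}

#' Maximum-likelihood exponent of a truncated power law
#'
#' Fits the exponent e of the density K t^e on [t_min, t_max] to observed
#' durations by numerically maximizing the truncation-aware log-likelihood.
#'
#' @param x Observed durations, all inside [t_min, t_max] (values outside
#'   are clamped to the bounds).
#' @param t_min,t_max Truncation bounds (0 < t_min < t_max).
#' @param interval Search interval for the exponent.
#' @return The fitted exponent (a negative number; -1.5 for the plume
#'   default).
#' @export
fit_powerlaw_exponent <- function(x, t_min, t_max, interval = c(-4, -1.0001)) {
  if (!(t_min > 0 && t_min < t_max)) {
    stop("need 0 < t_min < t_max", call. = FALSE)
  }
  x <- pmin(pmax(x, t_min), t_max)
  slx <- sum(log(x))
  n <- length(x)
  negll <- function(e) {
    e1 <- e + 1
    logK <- log(-e1) - log(t_min^e1 - t_max^e1)
    -(n * logK + e * slx)
  }
  stats::optimize(negll, interval)$minimum
}

#' @export
print.plume_stats <- function(x, ...) {
  cat(sprintf("plume_stats: intermittency a=%.3f b=%.3f | mean conc a=%.3g b=%.3g\n",
              x$intermittency[1], x$intermittency[2],
              x$mean_conc[1], x$mean_conc[2]))
  cat(sprintf("  realized correlation %.3f | whiff-duration exponent %.3f (n=%d)\n",
              x$rho_realized, x$exponent_hat, x$n_whiffs))
  invisible(x)
}
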