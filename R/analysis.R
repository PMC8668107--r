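#' Spike density function
#'
#' Kernel-smoothed firing-rate estimate.  Each spike contributes an
#' alpha-function kernel k(th) = th * exp(-th / tau) / tau^2, supported for
#' th >= 0 with th = t - t_spike + tau, so the kernel starts rising one tau
#' before the spike, peaks exactly at the spike time, and integrates to 1.
#' Per-neuron traces are computed on a regular grid and the population
#' trace is their mean (silent neurons included).
#'
#' @param rec A \code{"spike_record"}.
#' @param population Population label to extract (e.g. "ORN_a", "PN_b").
#' @param tau Kernel time scale (ms), default 20.
#' @param dt_grid Output grid resolution (ms), default 1.
#' @param t_total Trace end (ms); defaults to the record's duration.
#' @param n_neurons Number of neurons in the population; defaults to the
#'   record's \code{n_per_pop} attribute.
#' @return A \code{"rate_trace"}: list with \code{t} (ms), \code{rates}
#'   (n_neurons x n_t matrix, Hz), \code{rate} (population mean, Hz) and
#'   \code{population}.
#' @export
sdf <- function(rec, population, tau = 20, dt_grid = 1, t_total = NULL,
                n_neurons = NULL) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (is.null(t_total)) t_total <- attr(rec, "t_total")
  if (is.null(n_neurons)) n_neurons <- attr(rec, "n_per_pop")[[population]]
  if (is.null(t_total) || is.null(n_neurons)) {
    stop("t_total and n_neurons must be available", call. = FALSE)
  }
  grid <- seq(0, t_total, by = dt_grid)
  n_t <- length(grid)
  if (n_t == 0) stop("empty grid", call. = FALSE)
  sub <- rec[rec$population == population, , drop = FALSE]
  # kernel sampled on the grid, th >= 0, truncated at 10 tau
  th <- seq(0, 10 * tau, by = dt_grid)
  kern <- th * exp(-th / tau) / tau^2        # 1/ms, unit area
  shift <- round(tau / dt_grid)              # kernel onset precedes spike
  rates <- matrix(0, n_neurons, n_t)
  for (j in seq_len(n_neurons)) {
    ts <- sub$time[sub$neuron == j]
    if (length(ts) == 0) next
    bins <- pmin(pmax(floor(ts / dt_grid) + 1, 1), n_t)
    counts <- tabulate(bins, nbins = n_t)
    conv <- stats::convolve(counts, rev(kern), type = "open")
    # conv[i] corresponds to th = 0 at the spike bin; shift left by tau
    from <- 1 + shift
    take <- conv[from:(from + n_t - 1)]
    rates[j, ] <- 1000 * take                # 1/ms -> Hz
  }
  structure(list(t = grid, rates = rates, rate = colMeans(rates),
                 population = population, tau = tau),
            class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("rate_trace [%s]: %d neurons, t in [%g, %g] ms, peak %.1f Hz\n",
              x$population, nrow(x$rates), min(x$t), max(x$t), max(x$rate)))
  invisible(x)
}

window_idx <- function(trace, window) {
  if (window[1] < min(trace$t) || window[2] > max(trace$t)) {
    stop("window outside trace", call. = FALSE)
  }
  which(trace$t >= window[1] & trace$t <= window[2])
}

#' Maximum and average activity in a response window
#'
#' \code{max_activity} takes each neuron's maximum smoothed rate within the
#' window (by default the 200 ms following stimulus onset) and averages
#' across the neurons of the population; \code{avg_activity} does the same
#' with the within-window mean rate.
#'
#' @param trace A \code{"rate_trace"}.
#' @param onset Stimulus onset (ms).
#' @param window_ms Window length after onset (ms), default 200.
#' @param window Explicit window \code{c(from, to)} (ms); overrides
#'   \code{onset}/\code{window_ms}.
#' @return Activity in Hz.
#' @export
max_activity <- function(trace, onset = 0, window_ms = 200,
                         window = c(onset, onset + window_ms)) {
  idx <- window_idx(trace, window)
  mean(apply(trace$rates[, idx, drop = FALSE], 1, max))
}

#' @rdname max_activity
#' @export
avg_activity <- function(trace, onset = 0, window_ms = 200,
                         window = c(onset, onset + window_ms)) {
  idx <- window_idx(trace, window)
  mean(trace$rates[, idx, drop = FALSE])
}

#' Supra-threshold ("peak") activity
#'
#' Integrated firing rate over the epochs in which a neuron's rate exceeds
#' the threshold, averaged across neurons.  With the rate in Hz and time in
#' ms the integral is divided by 1000, so the value is a supra-threshold
#' spike count (Hz * s).
#'
#' @param trace A \code{"rate_trace"}.
#' @param threshold Rate threshold (Hz); typical values 50, 100, 150.
#' @return Mean supra-threshold integral per neuron (Hz * s).
#' @export
peak_activity <- function(trace, threshold = 100) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  dt <- trace$t[2] - trace$t[1]
  per_neuron <- apply(trace$rates, 1, function(r) {
    sum(r[r > threshold]) * dt / 1000
  })
  mean(per_neuron)
}

#' Mixture-ratio encoding error
#'
#' Squared relative distance between the response ratio and the
#' concentration ratio: err = ((R_pn - R_conc) / (R_pn + R_conc))^2.
#' Zero iff the response ratio equals the concentration ratio; tends to 1
#' as the two diverge.
#'
#' @param R_pn Response ratio nu_b / nu_a (> 0).
#' @param R_conc Peak-concentration ratio (> 0).
#' @return Error in [0, 1].
#' @examples
#' encoding_error(1, 3)  # 0.25
#' @export
encoding_error <- function(R_pn, R_conc) {
  if (any(R_pn <= 0) || any(R_conc <= 0)) {
    stop("ratios must be positive", call. = FALSE)
  }
  ((R_pn - R_conc) / (R_pn + R_conc))^2
}

#' Correlation between concentration ratio and response ratio
#'
#' @param R_conc Concentration ratios (>= 3 points).
#' @param R_pn Matching response ratios.
#' @param method "pearson" (default) or "spearman".
#' @return Correlation coefficient.
#' @export
ratio_correlation <- function(R_conc, R_pn, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(R_conc) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(R_pn) == 0 || stats::sd(R_conc) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(R_conc, R_pn, method = method)
}

#' Interference and encoding distances on peak-activity curves
#'
#' Given supra-threshold PN activity as a function of plume correlation for
#' each circuit variant, computes for each non-control variant x:
#' \code{d_interference} = p_ctrl(0) - p_x(0), how much the mechanism
#' suppresses responses to uncorrelated (separate-source) plumes, and
#' \code{d_encoding} = p_x(0) - p_x(1), how strongly the response separates
#' uncorrelated from fully correlated (single-source) plumes.
#'
#' @param df Data frame with columns \code{variant}, \code{rho} and
#'   \code{peak}; several rows per (variant, rho) are averaged.
#' @return Data frame with one row per non-control variant and columns
#'   \code{variant}, \code{d_interference}, \code{d_encoding}.
#' @export
correlation_encoding_distances <- function(df) {
  stopifnot(all(c("variant", "rho", "peak") %in% names(df)))
  endpoint <- function(v, which_rho) {
    sub <- df[df$variant == v, ]
    if (nrow(sub) == 0) stop("missing variant ", v, call. = FALSE)
    target <- if (which_rho == "lo") min(df$rho) else max(df$rho)
    if (which_rho == "lo" && target > 0.1) {
      stop("curves must include correlation near 0", call. = FALSE)
    }
    if (which_rho == "hi" && target < 0.9) {
      stop("curves must include correlation near 1", call. = FALSE)
    }
    mean(sub$peak[sub$rho == target])
  }
  ctrl0 <- endpoint("control", "lo")
  vars <- setdiff(unique(df$variant), "control")
  out <- lapply(vars, function(v) {
    data.frame(variant = v,
               d_interference = ctrl0 - endpoint(v, "lo"),
               d_encoding = endpoint(v, "lo") - endpoint(v, "hi"))
  })
  do.call(rbind, out)
}

#' Fit the PN-versus-ORN saturation curve
#'
#' PN firing rate as a function of ORN firing rate follows a sigmoid with
#' fixed exponent 1.5: nu_pn = nu_max * nu_orn^1.5 / (sigma^1.5 +
#' nu_orn^1.5).  Least-squares fit of nu_max and sigma.
#'
#' @param nu_orn,nu_pn Paired mean firing rates (Hz), >= 3 points spanning
#'   the saturating regime.
#' @return List with \code{nu_max}, \code{sigma}, \code{r_squared} and
#'   \code{fitted}.
#' @export
fit_pn_sigmoid <- function(nu_orn, nu_pn) {
  if (length(nu_orn) < 3) stop("need at least 3 points", call. = FALSE)
  if (all(nu_pn == 0)) {
    return(list(nu_max = 0, sigma = NA_real_, r_squared = 1,
                fitted = rep(0, length(nu_pn))))
  }
  d <- data.frame(x = nu_orn, y = nu_pn)
  fit <- minpack.lm::nlsLM(
    y ~ nu_max * x^1.5 / (sigma^1.5 + x^1.5), data = d,
    start = list(nu_max = max(nu_pn), sigma = max(stats::median(nu_orn), 1)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  pred <- stats::predict(fit)
  ss_res <- sum((nu_pn - pred)^2)
  ss_tot <- sum((nu_pn - mean(nu_pn))^2)
  est <- stats::coef(fit)
  list(nu_max = unname(est["nu_max"]), sigma = unname(est["sigma"]),
       r_squared = 1 - ss_res / ss_tot, fitted = pred)
}

#' Onset-to-peak latency of a population response
#'
#' @param trace A \code{"rate_trace"}.
#' @param onset Stimulus onset (ms).
#' @param search_ms How far after onset to search for the peak (ms).
#' @return Latency from onset to the maximum of the population rate (ms).
#' @export
onset_to_peak_latency <- function(trace, onset, search_ms = 300) {
  idx <- window_idx(trace, c(onset, min(onset + search_ms, max(trace$t))))
  trace$t[idx][which.max(trace$rate[idx])] - onset
}

#' Time for a ramp response to settle to a plateau
#'
#' Smooths the population-rate derivative and returns the first time after
#' stimulus onset at which its magnitude falls below \code{frac} of its
#' peak value and stays there for at least \code{hold_ms}.
#'
#' @param trace A \code{"rate_trace"}.
#' @param onset Stimulus onset (ms).
#' @param frac Plateau criterion as a fraction of the peak slope.
#' @param hold_ms Time the criterion must hold (ms).
#' @param smooth_ms Width of the moving-average smoothing of the
#'   derivative (ms).
#' @param search_end Last time considered (ms); defaults to trace end.
#' @return Plateau onset time measured from stimulus onset (ms), or NA if
#'   never reached.
#' @export
plateau_time <- function(trace, onset, frac = 0.05, hold_ms = 200,
                         smooth_ms = 50, search_end = max(trace$t)) {
  dt <- trace$t[2] - trace$t[1]
  idx <- window_idx(trace, c(onset, search_end))
  r <- trace$rate[idx]
  t <- trace$t[idx]
  dr <- diff(r) / dt
  k <- max(1, round(smooth_ms / dt))
  dr_s <- as.numeric(stats::filter(dr, rep(1 / k, k), sides = 2))
  ok <- !is.na(dr_s)
  peak_slope <- max(abs(dr_s[ok]))
  below <- abs(dr_s) < frac * peak_slope
  below[is.na(below)] <- TRUE
  hold <- max(1, round(hold_ms / dt))
  # require the criterion to hold from i for `hold` consecutive samples
  run <- rev(cumsum(rev(as.integer(!below))))
  for (i in seq_len(length(below) - hold)) {
    if (below[i] && run[i] - run[i + hold] == 0) {
      return(t[i] - onset)
    }
  }
  NA_real_
}

#' Detection thresholds and dynamic range of a dose-response curve
#'
#' The lower threshold C_l is the concentration at which the response
#' first reaches 10\% of the curve's maximum, and the higher threshold C_h
#' where it first reaches 90\%; both use log-linear interpolation between
#' grid points and a "first crossing" rule so they are well defined even
#' for non-monotonic (peak-and-plateau) curves.  The dynamic range is
#' log10(C_h / C_l).
#'
#' @param conc Concentration grid (increasing).
#' @param resp Response at each concentration (e.g. maximum activity, Hz).
#' @param lo,hi Threshold fractions of the maximum response.
#' @param baseline Spontaneous-activity level subtracted from the curve
#'   before thresholding; defaults to the response at the lowest
#'   concentration.
#' @return List with \code{C_l}, \code{C_h}, \code{dynamic_range} and
#'   \code{monotonic} (TRUE if the baseline-subtracted curve never falls
#'   more than 10\% below its maximum after the peak).
#' @export
dose_response_thresholds <- function(conc, resp, lo = 0.1, hi = 0.9,
                                     baseline = resp[1]) {
  stopifnot(length(conc) == length(resp), !is.unsorted(conc))
  resp <- resp - baseline
  rmax <- max(resp)
  first_crossing <- function(level) {
    above <- resp >= level
    i <- which(above)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(conc[1])
    # log-linear interpolation in concentration
    f <- (level - resp[i - 1]) / (resp[i] - resp[i - 1])
    10^(log10(conc[i - 1]) + f * (log10(conc[i]) - log10(conc[i - 1])))
  }
  C_l <- first_crossing(lo * rmax)
  C_h <- first_crossing(hi * rmax)
  ipk <- which.max(resp)
  mono <- TRUE
  if (ipk < length(resp)) {
    mono <- min(resp[ipk:length(resp)]) >= 0.9 * rmax
  }
  if (is.na(C_l) || is.na(C_h)) {
    stop("thresholds not bracketed by the concentration grid", call. = FALSE)
  }
  list(C_l = C_l, C_h = C_h, dynamic_range = log10(C_h / C_l),
       monotonic = mono)
}
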