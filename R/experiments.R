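#' Step-response experiment
#'
#' Simulates the ORN population response to a rectangular odor step
#' (default 500 ms at concentration 2e-3 on channel A after a 500 ms
#' settle period) and measures the onset-to-peak latency and peak rate of
#' the population spike-density function per trial.
#'
#' @param params Model parameters.
#' @param variant Circuit variant (ORN stage only; default control).
#' @param conc Step concentration (channel A).
#' @param duration Step duration (ms).
#' @param onset Step onset (ms).
#' @param n_trials Number of independent trials.
#' @param seed Base seed; trial k uses seed + k - 1.
#' @param dt Integration step (ms).
#' @return Data frame: \code{trial}, \code{latency_ms}, \code{peak_hz}.
#' @export
experiment_step_response <- function(params = default_params(),
                                     variant = make_variant("control"),
                                     conc = 2e-3, duration = 500,
                                     onset = 500, n_trials = 10, seed = 1,
                                     dt = 0.1) {
  w <- make_step(conc, 0, onset = onset, duration = duration,
                 t_total = onset + duration + 300, dt = dt)
  out <- lapply(seq_len(n_trials), function(k) {
    rec <- run_sensilla(w, params, variant, seed = seed + k - 1)
    tr <- sdf(rec, "ORN_a")
    data.frame(trial = k,
               latency_ms = onset_to_peak_latency(tr, onset),
               peak_hz = max(tr$rate))
  })
  do.call(rbind, out)
}

#' Ramp-response experiment
#'
#' Drives the ORN population with a linear concentration ramp (default
#' reaching 2e-3 over 2 s) and measures when the population rate settles
#' to a plateau: the first time after onset at which the smoothed rate
#' derivative stays below 5\% of its peak value.
#'
#' @inheritParams experiment_step_response
#' @param conc_end Concentration reached at the end of the ramp.
#' @param duration Ramp duration (ms).
#' @return Data frame: \code{trial}, \code{plateau_ms}.
#' @export
experiment_ramp_response <- function(params = default_params(),
                                     variant = make_variant("control"),
                                     conc_end = 2e-3, duration = 2000,
                                     onset = 500, n_trials = 10, seed = 1,
                                     dt = 0.1) {
  w <- make_ramp(conc_end / duration, 0, onset = onset, duration = duration,
                 t_total = onset + duration, dt = dt)
  out <- lapply(seq_len(n_trials), function(k) {
    rec <- run_sensilla(w, params, variant, seed = seed + k - 1)
    tr <- sdf(rec, "ORN_a")
    data.frame(trial = k,
               plateau_ms = plateau_time(tr, onset,
                                         search_end = onset + duration))
  })
  do.call(rbind, out)
}

default_variants <- function(omega_nsi = 0.6, alpha_ln = 0.6) {
  list(control = make_variant("control"),
       NSI = make_variant("NSI", omega_nsi = omega_nsi),
       LN = make_variant("LN", alpha_ln = alpha_ln),
       mix = make_variant("mix", omega_nsi = omega_nsi, alpha_ln = alpha_ln))
}

# Run the four variants on one waveform with seed-matched noise.  The ORN
# stage depends on the variant only through omega_nsi, so control/LN share
# one ORN run and NSI/mix another, exactly as the circuit logic implies.
run_variants_matched <- function(w, params, variants, seed,
                                 sensitivity = diag(2)) {
  omegas <- vapply(variants, function(v) v$omega_nsi, numeric(1))
  orn_by_omega <- list()
  for (om in unique(omegas)) {
    vtmp <- make_variant("mix", omega_nsi = om, alpha_ln = 0)
    if (om == 0) vtmp <- make_variant("control")
    set.seed(seed)
    orn_by_omega[[as.character(om)]] <-
      run_sensilla(w, params, vtmp, seed = NULL, sensitivity = sensitivity)
  }
  out <- list()
  for (nm in names(variants)) {
    v <- variants[[nm]]
    orn <- orn_by_omega[[as.character(v$omega_nsi)]]
    set.seed(seed + 10000L)
    al <- run_network(orn, params, v, seed = NULL)
    out[[nm]] <- list(orn = orn, al = al)
  }
  out
}

#' Mixture-ratio encoding experiment
#'
#' Stimulates both channels with synchronous triangular pulses whose peak
#' concentrations have a prescribed ratio, across circuit variants, and
#' measures ORN and PN response ratios and the encoding error.  The
#' default ratio grid is \{1, 2, 3, 5, 7, 10\} and the weaker odorant's
#' peak concentration is scanned over six log-spaced values up to 5e-3.
#'
#' @param params Model parameters.
#' @param variants Named list of \code{"variant_spec"} objects (default:
#'   all four).
#' @param concs Peak concentrations of the weaker odorant (channel A).
#' @param ratios Concentration ratios (channel B peak = ratio * channel A
#'   peak).
#' @param duration Triangle duration (ms).
#' @param n_trials Trials per condition.
#' @param seed Base seed.
#' @param measure "max" (default) or "avg" activity read-out.
#' @param dt Integration step (ms).
#' @return Tidy data frame with one row per (variant, conc, ratio, trial):
#'   response ratios \code{R_orn}, \code{R_pn}, the concentration ratio
#'   \code{R_conc} and the encoding error \code{err_enc}.
#' @export
experiment_ratio_encoding <- function(params = default_params(),
                                      variants = default_variants(),
                                      concs = signif(10^seq(log10(2e-4),
                                                            log10(5e-3),
                                                            length.out = 6), 3),
                                      ratios = c(1, 2, 3, 5, 7, 10),
                                      duration = 50, n_trials = 10, seed = 1,
                                      measure = c("max", "avg"), dt = 0.1) {
  measure <- match.arg(measure)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  act <- if (measure == "max") max_activity else avg_activity
  onset <- 500
  rows <- list()
  i <- 0
  for (conc in concs) {
    for (ratio in ratios) {
      w <- make_triangles(conc, conc * ratio, duration = duration,
                          delay = 0, onset = onset,
                          t_total = onset + duration + 450, dt = dt)
      for (k in seq_len(n_trials)) {
        trial_seed <- seed + 997L * i + k
        res <- run_variants_matched(w, params, variants, trial_seed)
        for (nm in names(res)) {
          orn_a <- act(sdf(res[[nm]]$orn, "ORN_a"), onset)
          orn_b <- act(sdf(res[[nm]]$orn, "ORN_b"), onset)
          pn_a <- act(sdf(res[[nm]]$al, "PN_a"), onset)
          pn_b <- act(sdf(res[[nm]]$al, "PN_b"), onset)
          rows[[length(rows) + 1]] <- data.frame(
            variant = nm, conc_weak = conc, R_conc = ratio, trial = k,
            nu_orn_a = orn_a, nu_orn_b = orn_b,
            nu_pn_a = pn_a, nu_pn_b = pn_b,
            R_orn = orn_b / orn_a, R_pn = pn_b / pn_a,
            err_enc = if (pn_a > 0 && pn_b > 0) {
              encoding_error(pn_b / pn_a, ratio)
            } else NA_real_)
        }
      }
      i <- i + 1
    }
  }
  do.call(rbind, rows)
}

#' Per-variant coding-error summary
#'
#' Averages the encoding error over the concentration-ratio grid and
#' trials, for each (variant, duration-independent) concentration of the
#' weaker odorant.
#'
#' @param results Output of \code{\link{experiment_ratio_encoding}}.
#' @return Data frame: \code{variant}, \code{conc_weak},
#'   \code{mean_err_enc}.
#' @export
coding_error_summary <- function(results) {
  agg <- stats::aggregate(err_enc ~ variant + conc_weak, data = results,
                          FUN = mean, na.rm = TRUE)
  names(agg)[names(agg) == "err_enc"] <- "mean_err_enc"
  agg[order(agg$conc_weak, agg$variant), ]
}

#' Asynchronous-pulse experiment
#'
#' Two equal-amplitude triangular pulses, channel B delayed relative to
#' channel A, across circuit variants.  The response of each glomerulus is
#' measured in the 200 ms window following its own channel's pulse onset,
#' and the ratio R_PN = nu_b / nu_a quantifies how much the response to
#' the delayed odorant is suppressed by the response to the first.
#'
#' @param params Model parameters.
#' @param variants Named list of variants.
#' @param delays Channel-B onset delays (ms).
#' @param duration Pulse duration (ms).
#' @param conc Peak concentration (both channels).
#' @param n_trials Trials per delay.
#' @param seed Base seed.
#' @param dt Integration step (ms).
#' @return Tidy data frame: \code{variant}, \code{delay}, \code{trial},
#'   \code{nu_pn_a}, \code{nu_pn_b}, \code{R_pn}, \code{R_orn}.
#' @export
experiment_async_pulses <- function(params = default_params(),
                                    variants = default_variants(),
                                    delays = c(0, 50, 100, 200, 500),
                                    duration = 50, conc = 1e-3,
                                    n_trials = 10, seed = 1, dt = 0.1) {
  onset <- 500
  rows <- list()
  i <- 0
  for (delay in delays) {
    w <- make_triangles(conc, conc, duration = duration, delay = delay,
                        onset = onset,
                        t_total = onset + delay + duration + 450, dt = dt)
    for (k in seq_len(n_trials)) {
      trial_seed <- seed + 991L * i + k
      res <- run_variants_matched(w, params, variants, trial_seed)
      for (nm in names(res)) {
        pn_a <- max_activity(sdf(res[[nm]]$al, "PN_a"), onset)
        pn_b <- max_activity(sdf(res[[nm]]$al, "PN_b"), onset + delay)
        orn_a <- max_activity(sdf(res[[nm]]$orn, "ORN_a"), onset)
        orn_b <- max_activity(sdf(res[[nm]]$orn, "ORN_b"), onset + delay)
        rows[[length(rows) + 1]] <- data.frame(
          variant = nm, delay = delay, trial = k,
          nu_pn_a = pn_a, nu_pn_b = pn_b,
          R_pn = pn_b / pn_a, R_orn = orn_b / orn_a)
      }
    }
    i <- i + 1
  }
  do.call(rbind, rows)
}

#' Plume-correlation experiment
#'
#' Generates pairs of naturalistic plumes over a grid of target
#' correlations, runs all circuit variants on each (seed-matched), and
#' measures average ORN/PN activity over the whole series plus the
#' supra-threshold ("peak") PN activity at 50/100/150 Hz.
#'
#' @param params Model parameters.
#' @param variants Named list of variants.
#' @param rho_grid Target copula correlations.
#' @param t_total_s Plume duration in seconds per run.
#' @param n_seeds Independent plume realizations per correlation.
#' @param whiff_max Maximum whiff duration (s).
#' @param mean_conc Mean whiff concentration.
#' @param seed Base seed.
#' @param dt Integration step (ms).
#' @return Tidy data frame: one row per (variant, rho, seed) with
#'   \code{rho_realized}, \code{avg_orn}, \code{avg_pn}, \code{peak50},
#'   \code{peak100}, \code{peak150}.
#' @export
experiment_plume_correlation <- function(params = default_params(),
                                         variants = default_variants(),
                                         rho_grid = c(0, 1 / 3, 2 / 3, 1),
                                         t_total_s = 50, n_seeds = 5,
                                         whiff_max = 3, mean_conc = 1.5e-3,
                                         seed = 1, dt = 0.1) {
  rows <- list()
  i <- 0
  for (rho in rho_grid) {
    for (k in seq_len(n_seeds)) {
      plume_seed <- seed + 977L * i + k
      set.seed(plume_seed)
      spec <- plume_spec(rho_target = rho, t_total = t_total_s,
                         whiff_max = whiff_max, mean_conc = mean_conc,
                         dt = dt)
      w <- generate_plume_pair(spec)
      st <- measure_plume_stats(w)
      res <- run_variants_matched(w, params, variants, plume_seed + 1L)
      for (nm in names(res)) {
        al <- res[[nm]]$al
        orn <- res[[nm]]$orn
        t_tot <- attr(al, "t_total")
        rate_of <- function(rec, pops) {
          np <- attr(rec, "n_per_pop")
          sum(rec$population %in% pops) /
            sum(np[pops]) / t_tot * 1000
        }
        tr_a <- sdf(al, "PN_a")
        tr_b <- sdf(al, "PN_b")
        pk <- function(thr) {
          (peak_activity(tr_a, thr) + peak_activity(tr_b, thr)) / 2
        }
        rows[[length(rows) + 1]] <- data.frame(
          variant = nm, rho = rho, seed_rep = k,
          rho_realized = st$rho_realized,
          avg_orn = rate_of(orn, c("ORN_a", "ORN_b")),
          avg_pn = rate_of(al, c("PN_a", "PN_b")),
          peak50 = pk(50), peak100 = pk(100), peak150 = pk(150))
      }
    }
    i <- i + 1
  }
  do.call(rbind, rows)
}

#' Dynamic-range scan of a co-housed ORN pair
#'
#' A single odorant (channel A) drives both ORNs of a sensillum; ORN a
#' with gain 1 and ORN b with gain \code{sens_b} <= 1, so the pair's
#' sensitivity distance is about -log10(sens_b) orders of magnitude.
#' Scans a log-spaced concentration grid with triangular pulses, builds
#' the dose-response curve (maximum activity) of each ORN and of the
#' two-ORN average, and derives detection thresholds and dynamic range.
#'
#' @param params Model parameters.
#' @param variant Circuit variant (control or NSI are the meaningful
#'   choices; only the ORN stage is simulated).
#' @param sens_b Gain of ORN b for the odorant, in (0, 1].
#' @param conc_grid Concentration grid (increasing, log-spaced).
#' @param duration Pulse duration (ms); 10-200 ms typical.
#' @param n_trials Trials averaged per concentration.
#' @param seed Base seed.
#' @param dt Integration step (ms).
#' @return List with \code{curve} (data frame: conc, resp_a, resp_b,
#'   resp_avg), \code{thresholds} (from the averaged curve),
#'   \code{thresholds_a}, \code{thresholds_b} (isolated-ORN control
#'   curves are required for these to be meaningful), and
#'   \code{sensitivity_distance} = log10(C_l_b / C_l_a) from the
#'   per-ORN curves.
#' @export
dynamic_range_scan <- function(params = default_params(),
                               variant = make_variant("control"),
                               sens_b = 1,
                               conc_grid = 10^seq(-5, -1.5, length.out = 12),
                               duration = 50, n_trials = 3, seed = 1,
                               dt = 0.1) {
  if (sens_b <= 0 || sens_b > 1) stop("sens_b must be in (0, 1]", call. = FALSE)
  onset <- 500
  sens <- rbind(c(1, 0), c(sens_b, 0))
  rows <- lapply(seq_along(conc_grid), function(i) {
    conc <- conc_grid[i]
    w <- make_triangles(conc, 0, duration = duration, delay = 0,
                        onset = onset, t_total = onset + duration + 450,
                        dt = dt)
    ra <- rb <- numeric(n_trials)
    for (k in seq_len(n_trials)) {
      rec <- run_sensilla(w, params, variant, seed = seed + 31L * i + k,
                          sensitivity = sens)
      ra[k] <- max_activity(sdf(rec, "ORN_a"), onset)
      rb[k] <- max_activity(sdf(rec, "ORN_b"), onset)
    }
    data.frame(conc = conc, resp_a = mean(ra), resp_b = mean(rb),
               resp_avg = (mean(ra) + mean(rb)) / 2)
  })
  curve <- do.call(rbind, rows)
  th_a <- dose_response_thresholds(curve$conc, curve$resp_a)
  th_b <- dose_response_thresholds(curve$conc, curve$resp_b)
  th_avg <- dose_response_thresholds(curve$conc, curve$resp_avg)
  list(curve = curve, thresholds = th_avg, thresholds_a = th_a,
       thresholds_b = th_b,
       sensitivity_distance = log10(th_b$C_l / th_a$C_l))
}

#' Run a named experiment and write its outputs
#'
#' Orchestration entry point used by the command-line interface: builds
#' the stimuli, runs the requested circuit variants, applies the analysis,
#' and writes a tidy CSV plus a JSON manifest (experiment, seed, variants,
#' parameter values, timings) into \code{out_dir}.
#'
#' @param name One of "step_response", "ratio_encoding", "async_pulses",
#'   "plume_correlation", "dynamic_range".
#' @param out_dir Output directory (created if missing); NULL skips
#'   writing.
#' @param params Model parameters.
#' @param n_trials Trials (where applicable).
#' @param seed Base seed.
#' @param ... Passed to the specific experiment function.
#' @return The experiment's result data frame (invisibly when writing).
#' @export
run_experiment <- function(name = c("step_response", "ratio_encoding",
                                    "async_pulses", "plume_correlation",
                                    "dynamic_range"),
                           out_dir = NULL, params = default_params(),
                           n_trials = 10, seed = 1, ...) {
  name <- match.arg(name)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(name,
    step_response = experiment_step_response(params = params,
                                             n_trials = n_trials,
                                             seed = seed, ...),
    ratio_encoding = experiment_ratio_encoding(params = params,
                                               n_trials = n_trials,
                                               seed = seed, ...),
    async_pulses = experiment_async_pulses(params = params,
                                           n_trials = n_trials,
                                           seed = seed, ...),
    plume_correlation = experiment_plume_correlation(params = params,
                                                     seed = seed, ...),
    dynamic_range = {
      scan <- dynamic_range_scan(params = params, seed = seed, ...)
      cbind(scan$curve,
            dynamic_range = scan$thresholds$dynamic_range,
            sensitivity_distance = scan$sensitivity_distance)
    })
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv_path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(res, csv_path, row.names = FALSE)
    manifest <- list(experiment = name, seed = seed, n_trials = n_trials,
                     elapsed_s = round(elapsed, 2),
                     package_version = as.character(utils::packageVersion("olfsim")),
                     params = unclass_deep(params))
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(name, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' Rank circuit variants on an encoding metric
#'
#' Summarizes per-trial metric values by variant with a bootstrap
#' confidence interval over trials, and orders variants from best
#' (smallest metric, e.g. coding error) to worst.
#'
#' @param results Tidy data frame with columns \code{variant},
#'   \code{trial} and the metric.
#' @param metric Column name to summarize (default "err_enc").
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @return Data frame ordered by mean metric: \code{variant},
#'   \code{mean}, \code{ci_lo}, \code{ci_hi}, \code{n}.
#' @export
compare_variants <- function(results, metric = "err_enc", n_boot = 2000,
                             conf = 0.95) {
  stopifnot(metric %in% names(results), "variant" %in% names(results))
  a <- (1 - conf) / 2
  out <- lapply(split(results, results$variant), function(sub) {
    x <- sub[[metric]]
    x <- x[is.finite(x)]
    boots <- replicate(n_boot, mean(sample(x, replace = TRUE)))
    data.frame(variant = sub$variant[1], mean = mean(x),
               ci_lo = unname(stats::quantile(boots, a)),
               ci_hi = unname(stats::quantile(boots, 1 - a)),
               n = length(x))
  })
  out <- do.call(rbind, out)
  out[order(out$mean), ]
}
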