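#' Two-channel stimulus waveforms
#'
#' A stimulus waveform holds odorant concentration time series for the two
#' odorant channels (A drives ORNs of type a, B drives type b) on a shared
#' uniform time grid.  Concentrations are in the same liquid-dilution (v/v)
#' proxy units as the transduction parameters.
#'
#' @param t Time grid (ms), uniform.
#' @param conc_a,conc_b Concentration per channel (>= 0), same length as
#'   \code{t}.
#' @param meta Named list describing the generator and its parameters.
#' @return An object of class \code{"stimulus_waveform"}: a list with
#'   \code{t}, \code{conc_a}, \code{conc_b}, \code{dt} and \code{meta}.
#' @export
stimulus_waveform <- function(t, conc_a, conc_b, meta = list()) {
  if (length(conc_a) != length(t) || length(conc_b) != length(t)) {
    stop("channel lengths must match the time grid", call. = FALSE)
  }
  if (any(conc_a < 0) || any(conc_b < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  dt <- if (length(t) > 1) t[2] - t[1] else NA_real_
  structure(list(t = t, conc_a = conc_a, conc_b = conc_b, dt = dt,
                 meta = meta),
            class = "stimulus_waveform")
}

#' @export
print.stimulus_waveform <- function(x, ...) {
  cat(sprintf("stimulus_waveform: %d samples, dt=%g ms, t in [%g, %g] ms\n",
              length(x$t), x$dt, min(x$t), max(x$t)))
  if (!is.null(x$meta$kind)) cat(sprintf("  generator: %s\n", x$meta$kind))
  cat(sprintf("  peak conc: a=%.3g, b=%.3g\n", max(x$conc_a), max(x$conc_b)))
  invisible(x)
}

time_grid <- function(t_total, dt) seq(0, t_total, by = dt)

#' Rectangular step stimulus
#'
#' A rectangular concentration pulse on each channel, zero elsewhere.
#'
#' @param peak_conc_a,peak_conc_b Plateau concentration per channel.
#' @param onset Stimulus onset (ms).
#' @param duration Step duration (ms), > 0.
#' @param t_total Total waveform duration (ms).
#' @param dt Grid step (ms).
#' @return A \code{"stimulus_waveform"}.
#' @examples
#' w <- make_step(1e-3, 0, onset = 100, duration = 500, t_total = 1000)
#' @export
make_step <- function(peak_conc_a, peak_conc_b = peak_conc_a, onset = 500,
                      duration = 500, t_total = onset + duration + 500,
                      dt = 0.1) {
  if (peak_conc_a < 0 || peak_conc_b < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (onset + duration > t_total) {
    stop("stimulus does not fit in t_total", call. = FALSE)
  }
  t <- time_grid(t_total, dt)
  on <- t >= onset & t < onset + duration
  stimulus_waveform(t, ifelse(on, peak_conc_a, 0), ifelse(on, peak_conc_b, 0),
                    meta = list(kind = "step", onset = onset,
                                duration = duration,
                                peak_conc_a = peak_conc_a,
                                peak_conc_b = peak_conc_b))
}

#' Linear ramp stimulus
#'
#' Concentration rises linearly from zero at \code{onset} with the given
#' slope over the stimulus window, and returns to zero afterwards.  Both
#' channels receive the same ramp scaled by their slopes.
#'
#' @param slope_a,slope_b Concentration increase per ms (>= 0).
#' @param onset Window start (ms).
#' @param duration Window length (ms); ramps of 2000 ms are typical.
#' @param t_total,dt Grid parameters (ms).
#' @return A \code{"stimulus_waveform"}.
#' @export
make_ramp <- function(slope_a, slope_b = 0, onset = 500, duration = 2000,
                      t_total = onset + duration + 500, dt = 0.1) {
  if (slope_a < 0 || slope_b < 0) stop("slope must be non-negative", call. = FALSE)
  if (onset + duration > t_total) stop("stimulus does not fit in t_total", call. = FALSE)
  t <- time_grid(t_total, dt)
  rel <- t - onset
  shape <- ifelse(rel >= 0 & rel <= duration, rel, 0)
  stimulus_waveform(t, slope_a * shape, slope_b * shape,
                    meta = list(kind = "ramp", onset = onset,
                                duration = duration, slope_a = slope_a,
                                slope_b = slope_b))
}

#' Parabolic stimulus
#'
#' Quadratic rise from zero: concentration a*(t - onset)^2 inside the
#' stimulus window.
#'
#' @param accel_a,accel_b Quadratic coefficient (concentration / ms^2).
#' @inheritParams make_ramp
#' @return A \code{"stimulus_waveform"}.
#' @export
make_parabola <- function(accel_a, accel_b = 0, onset = 500, duration = 2000,
                          t_total = onset + duration + 500, dt = 0.1) {
  if (accel_a < 0 || accel_b < 0) stop("coefficient must be non-negative", call. = FALSE)
  if (onset + duration > t_total) stop("stimulus does not fit in t_total", call. = FALSE)
  t <- time_grid(t_total, dt)
  rel <- t - onset
  shape <- ifelse(rel >= 0 & rel <= duration, rel^2, 0)
  stimulus_waveform(t, accel_a * shape, accel_b * shape,
                    meta = list(kind = "parabola", onset = onset,
                                duration = duration, accel_a = accel_a,
                                accel_b = accel_b))
}

#' Triangular odorant pulses
#'
#' Each channel receives an isosceles triangular concentration pulse: linear
#' rise over \code{duration/2} to the stated peak, then a symmetric linear
#' decay.  Channel B's pulse starts \code{delay} ms after channel A's.
#' These pulses mimic individual whiffs in a plume; durations of 10-200 ms
#' (up to 500 ms) and delays of 0-500 ms cover the experimental range.
#'
#' @param peak_conc_a,peak_conc_b Apex concentration per channel (a peak of
#'   0 silences the channel).
#' @param duration Pulse base duration (ms), > 0.
#' @param delay Onset delay of channel B after channel A (ms, >= 0).
#' @param onset Onset of channel A's pulse (ms); the default 500 ms
#'   pre-stimulus settle time lets adaptation variables reach baseline.
#' @param t_total,dt Grid parameters (ms).
#' @return A \code{"stimulus_waveform"}.
#' @examples
#' w <- make_triangles(1e-3, 2e-3, duration = 50, delay = 0)
#' @export
make_triangles <- function(peak_conc_a, peak_conc_b = peak_conc_a,
                           duration = 50, delay = 0, onset = 500,
                           t_total = onset + delay + duration + 500,
                           dt = 0.1) {
  if (peak_conc_a < 0 || peak_conc_b < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (delay < 0) stop("delay must be >= 0", call. = FALSE)
  if (onset + delay + duration > t_total) {
    stop("t_total too short to contain both pulses", call. = FALSE)
  }
  t <- time_grid(t_total, dt)
  tri <- function(start, peak) {
    rel <- t - start
    half <- duration / 2
    shape <- pmax(0, 1 - abs(rel - half) / half)
    peak * shape
  }
  stimulus_waveform(t, tri(onset, peak_conc_a), tri(onset + delay, peak_conc_b),
                    meta = list(kind = "triangles", onset = onset,
                                duration = duration, delay = delay,
                                peak_conc_a = peak_conc_a,
                                peak_conc_b = peak_conc_b))
}

#' Write / read a waveform as CSV
#'
#' Plain-text round-trip format: columns \code{t}, \code{conc_a},
#' \code{conc_b}; a comment header line carries \code{dt} and the unit
#' convention.
#'
#' @param w A \code{"stimulus_waveform"}.
#' @param path File path.
#' @return \code{read_waveform_csv} returns the reconstructed waveform.
#' @export
write_waveform_csv <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stimulus_waveform dt_ms=%.17g conc_units=v/v", w$dt), con)
  utils::write.csv(data.frame(t = w$t, conc_a = w$conc_a, conc_b = w$conc_b),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  stimulus_waveform(d$t, d$conc_a, d$conc_b, meta = list(kind = "csv"))
}
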