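#' One forward-Euler step of the transduction stage
#'
#' Receptor binding follows a single Hill-type rate equation: the bound
#' fraction r increases at rate alpha_r * c^n * (1 - r) and unbinds at rate
#' beta_r * r.  The constant offset \code{c0} is added to the stimulus
#' concentration and produces spontaneous receptor activation.
#'
#' @param r Current bound-receptor fraction(s) in [0, 1].
#' @param c Odorant concentration (>= 0), before the \code{c0} offset.
#' @param tr Transduction parameter list (see \code{\link{default_params}}).
#' @param dt Step (ms).
#' @param use_c0 Add the spontaneous-activation offset (default TRUE).
#' @return Updated r, clipped to [0, 1].
#' @export
step_transduction <- function(r, c, tr, dt, use_c0 = TRUE) {
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  c_eff <- c + if (use_c0) tr$c0 else 0
  drive <- tr$alpha_r * c_eff^tr$n
  r2 <- r + dt * (drive * (1 - r) - tr$beta_r * r)
  pmin(pmax(r2, 0), 1)
}

#' Steady-state bound-receptor fraction
#'
#' Closed-form fixed point of the transduction equation at constant
#' concentration: r = a / (a + beta_r) with a = alpha_r * c^n.
#'
#' @inheritParams step_transduction
#' @return Steady-state r.
#' @export
transduction_steady_state <- function(c, tr, use_c0 = TRUE) {
  c_eff <- c + if (use_c0) tr$c0 else 0
  a <- tr$alpha_r * c_eff^tr$n
  a / (a + tr$beta_r)
}

#' Ephaptically shifted reversal potential
#'
#' The non-synaptic interaction between the two ORNs of a sensillum is
#' modeled as an activity-dependent shift of each neuron's receptor-current
#' reversal potential towards rest, proportional to the partner's
#' bound-receptor fraction:
#' V_rev' = V_rev - omega_nsi * r_other * (V_rev - V_rest).
#'
#' @param V_rev Unshifted reversal potential (mV).
#' @param V_rest Resting potential (mV).
#' @param omega_nsi Coupling strength in [0, 1].
#' @param r_other Partner ORN's bound-receptor fraction in [0, 1].
#' @return Effective reversal potential (mV).
#' @examples
#' nsi_reversal(0, -33, 0.6, 0.5)  # -9.9 mV
#' @export
nsi_reversal <- function(V_rev, V_rest, omega_nsi, r_other) {
  V_rev - omega_nsi * r_other * (V_rev - V_rest)
}

#' One step of the ORN spike generator
#'
#' Reference (pure R) single-neuron update used for testing and
#' exposition; \code{\link{run_sensilla}} performs the same update in
#' compiled code for whole populations.  The membrane integrates leak,
#' adaptation (reversal \code{V_K}) and receptor currents by forward Euler;
#' on crossing threshold the neuron spikes, resets to rest, holds for the
#' refractory period, and the adaptation variable y jumps by
#' \code{alpha_y}.
#'
#' @param state List with \code{V} (mV), \code{y} (unitless, >= 0) and
#'   \code{refr} (remaining refractory time, ms).
#' @param r_self This ORN's bound-receptor fraction.
#' @param r_other The co-housed ORN's bound-receptor fraction (drives the
#'   ephaptic shift).
#' @param orn ORN parameter list.
#' @param omega_nsi Ephaptic strength actually applied (0 disables).
#' @param dt Step (ms).
#' @param zeta Receptor-noise value added to \code{r_self} in the receptor
#'   current (default 0: deterministic).
#' @return List: updated \code{state} and logical \code{spiked}.
#' @export
step_orn <- function(state, r_self, r_other, orn, omega_nsi = orn$omega_nsi,
                     dt = 0.1, zeta = 0) {
  V <- state$V; y <- state$y; refr <- state$refr
  if (!is.finite(V) || !is.finite(y)) {
    stop("non-finite ORN state: integration blow-up", call. = FALSE)
  }
  if (refr > 0) {
    refr <- refr - dt
    V <- orn$V_rest
  } else {
    vrev <- nsi_reversal(orn$V_rev, orn$V_rest, omega_nsi, r_other)
    I <- orn$gl * (orn$V_rest - V) + orn$g_y * y * (orn$V_K - V) +
      orn$g_r * (r_self + zeta) * (vrev - V)
    V <- V + dt * I / orn$C
  }
  y <- y - dt * orn$beta_y * y
  spiked <- FALSE
  if (refr <= 0 && V > orn$theta) {
    spiked <- TRUE
    V <- orn$V_rest
    refr <- orn$tau_ref
    y <- y + orn$alpha_y
  }
  list(state = list(V = V, y = y, refr = refr), spiked = spiked)
}

#' Simulate a population of sensilla
#'
#' Runs \code{n_orn_per_type} sensilla, each housing one ORN of type a and
#' one of type b coupled by the ephaptic interaction.  By default type a
#' responds only to channel A of the waveform and type b only to channel B
#' (strict selectivity); the \code{sensitivity} matrix relaxes this for
#' dynamic-range experiments where one odorant drives both neurons with
#' different gains.  Receptor noise is an independent Ornstein-Uhlenbeck
#' process per ORN.
#'
#' @param waveform A \code{"stimulus_waveform"}.
#' @param params An \code{"olf_params"} set.
#' @param variant A \code{"variant_spec"}; its \code{omega_nsi} is applied
#'   (0 for control/LN variants).
#' @param seed Optional integer seed (\code{set.seed} is called when
#'   non-NULL; pass NULL to continue the current RNG stream).
#' @param sensitivity 2 x 2 matrix: entry [k, m] is the gain with which
#'   odorant channel m (A, B) drives ORN type k (a, b).  Default identity.
#' @return A \code{"spike_record"} data frame with columns
#'   \code{population} ("ORN_a"/"ORN_b"), \code{neuron} (1-based index
#'   within the population) and \code{time} (ms), plus attributes
#'   \code{t_total}, \code{dt} and \code{n_per_pop}.
#' @export
run_sensilla <- function(waveform, params, variant = make_variant("control"),
                         seed = NULL, sensitivity = diag(2)) {
  stopifnot(inherits(waveform, "stimulus_waveform"))
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  raw <- run_sensilla_cpp(waveform$conc_a, waveform$conc_b, waveform$dt,
                          params$transduction, params$orn,
                          params$layout$n_orn_per_type, variant$omega_nsi,
                          sensitivity)
  n <- params$layout$n_orn_per_type
  recs <- lapply(seq_along(raw), function(j) {
    ts <- raw[[j]]
    if (length(ts) == 0) return(NULL)
    type <- if ((j - 1) %% 2 == 0) "ORN_a" else "ORN_b"
    data.frame(population = type, neuron = (j - 1) %/% 2 + 1, time = ts)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(population = character(), neuron = integer(),
                      time = numeric())
  }
  spike_record(out, t_total = max(waveform$t), dt = waveform$dt,
               n_per_pop = c(ORN_a = n, ORN_b = n))
}

#' Construct a spike record
#'
#' @param df Data frame with columns \code{population}, \code{neuron},
#'   \code{time}.
#' @param t_total Simulated duration (ms).
#' @param dt Integration step used (ms).
#' @param n_per_pop Named integer vector: number of neurons per population
#'   (needed so silent neurons enter population averages).
#' @return The data frame with class \code{"spike_record"} and the three
#'   attributes attached.
#' @export
spike_record <- function(df, t_total, dt, n_per_pop) {
  stopifnot(all(c("population", "neuron", "time") %in% names(df)))
  attr(df, "t_total") <- t_total
  attr(df, "dt") <- dt
  attr(df, "n_per_pop") <- n_per_pop
  class(df) <- c("spike_record", "data.frame")
  df
}

#' @export
print.spike_record <- function(x, ...) {
  np <- attr(x, "n_per_pop")
  cat(sprintf("spike_record: %d spikes over %g ms\n", nrow(x),
              attr(x, "t_total")))
  for (p in names(np)) {
    n_sp <- sum(x$population == p)
    cat(sprintf("  %s: %d neurons, %d spikes (%.1f Hz mean)\n", p, np[[p]],
                n_sp, 1000 * n_sp / np[[p]] / attr(x, "t_total")))
  }
  invisible(x)
}

#' Write spikes as a two-column text file
#'
#' Format: neuron label (population:index) and spike time in ms, one spike
#' per line, tab-separated.
#'
#' @param rec A \code{"spike_record"}.
#' @param path Output path.
#' @export
write_spikes_txt <- function(rec, path) {
  utils::write.table(
    data.frame(neuron = paste0(rec$population, ":", rec$neuron),
               time_ms = rec$time),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
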