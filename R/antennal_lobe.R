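#' One step of a saturating synaptic activation
#'
#' Reference (pure R) update of the vesicle-release activation used by all
#' three synapse classes: a presynaptic spike increments the activation by
#' alpha * (1 - act) (saturating at 1), and it decays exponentially with
#' time constant tau otherwise.
#'
#' @param act Activation in [0, 1].
#' @param n_spikes Number of presynaptic spikes in this step.
#' @param alpha Release jump per spike.
#' @param tau Decay time constant (ms).
#' @param dt Step (ms).
#' @return Updated activation.
#' @export
step_synapse <- function(act, n_spikes, alpha, tau, dt) {
  act <- act - dt * act / tau
  if (n_spikes > 0) {
    for (k in seq_len(n_spikes)) act <- act + alpha * (1 - act)
  }
  act
}

#' Block connectivity of the two-glomerulus antennal lobe
#'
#' ORNs of one type all project to every PN of their glomerulus
#' (\code{w}); PNs excite every LN of their own glomerulus (\code{v}); LNs
#' inhibit every PN of the \emph{other} glomerulus and none of their own
#' (\code{u}).
#'
#' @param layout Layout list (see \code{\link{default_params}}).
#' @return List of 0/1 matrices \code{w} (PN x ORN), \code{v} (LN x PN)
#'   and \code{u} (PN x LN).
#' @export
build_connectivity <- function(layout) {
  n_orn <- layout$n_orn_per_type
  n_pn <- layout$n_pn_per_glom
  n_ln <- layout$n_ln_per_glom
  g <- layout$n_glom
  glom_of <- function(idx, per) (idx - 1) %/% per + 1
  w <- matrix(0, g * n_pn, g * n_orn)
  for (i in seq_len(g * n_pn)) {
    for (j in seq_len(g * n_orn)) {
      w[i, j] <- as.integer(glom_of(i, n_pn) == glom_of(j, n_orn))
    }
  }
  v <- matrix(0, g * n_ln, g * n_pn)
  for (i in seq_len(g * n_ln)) {
    for (j in seq_len(g * n_pn)) {
      v[i, j] <- as.integer(glom_of(i, n_ln) == glom_of(j, n_pn))
    }
  }
  u <- matrix(0, g * n_pn, g * n_ln)
  for (i in seq_len(g * n_pn)) {
    for (j in seq_len(g * n_ln)) {
      u[i, j] <- as.integer(glom_of(i, n_pn) != glom_of(j, n_ln))
    }
  }
  list(w = w, v = v, u = u)
}

#' Simulate the antennal lobe driven by ORN spikes
#'
#' Runs the two-glomerulus network of PNs (LIF with spike-rate adaptation
#' and white current noise) and LNs (LIF with noise, no adaptation),
#' coupled through saturating conductance-based synapses.  The variant's
#' \code{alpha_ln} sets the LN->PN release jump; at 0 (control and NSI
#' variants) the LN pathway is silent and PN spikes are identical to a
#' control run with the same seed.
#'
#' @param orn_spikes A \code{"spike_record"} of ORN spikes (populations
#'   "ORN_a"/"ORN_b").
#' @param params An \code{"olf_params"} set.
#' @param variant A \code{"variant_spec"}.
#' @param seed Optional integer seed (NULL continues the current stream).
#' @return A \code{"spike_record"} with populations "PN_a", "PN_b",
#'   "LN_a", "LN_b".
#' @export
run_network <- function(orn_spikes, params, variant = make_variant("control"),
                        seed = NULL) {
  stopifnot(inherits(orn_spikes, "spike_record"))
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  lay <- params$layout
  n_orn <- lay$n_orn_per_type
  t_total <- attr(orn_spikes, "t_total")
  dt <- attr(orn_spikes, "dt")
  # interleave back to neuron-major list: ORN_a 1..n, ORN_b 1..n
  sp_list <- vector("list", 2 * n_orn)
  for (j in seq_len(2 * n_orn)) sp_list[[j]] <- numeric(0)
  for (p in c("ORN_a", "ORN_b")) {
    off <- if (p == "ORN_a") 0 else n_orn
    sub <- orn_spikes[orn_spikes$population == p, ]
    if (nrow(sub)) {
      byn <- split(sub$time, sub$neuron)
      for (nm in names(byn)) {
        sp_list[[off + as.integer(nm)]] <- sort(byn[[nm]])
      }
    }
  }
  raw <- run_network_cpp(sp_list, t_total, dt, params$al$pn, params$al$ln,
                         params$al$syn, params$al$C, variant$alpha_ln,
                         n_orn, lay$n_pn_per_glom, lay$n_ln_per_glom)
  n_pn <- lay$n_pn_per_glom
  n_ln <- lay$n_ln_per_glom
  collect <- function(lst, per, prefix) {
    recs <- lapply(seq_along(lst), function(j) {
      ts <- lst[[j]]
      if (length(ts) == 0) return(NULL)
      g <- (j - 1) %/% per
      data.frame(population = paste0(prefix, c("a", "b")[g + 1]),
                 neuron = (j - 1) %% per + 1, time = ts)
    })
    do.call(rbind, recs)
  }
  out <- rbind(collect(raw$pn, n_pn, "PN_"), collect(raw$ln, n_ln, "LN_"))
  if (is.null(out)) {
    out <- data.frame(population = character(), neuron = integer(),
                      time = numeric())
  }
  spike_record(out, t_total = t_total, dt = dt,
               n_per_pop = c(PN_a = n_pn, PN_b = n_pn,
                             LN_a = n_ln, LN_b = n_ln))
}

#' Run the full circuit end-to-end
#'
#' Sensilla followed by the antennal lobe for one circuit variant.  A
#' single seed controls both stages; identical seed, waveform, parameters
#' and variant give bit-identical spike records.
#'
#' @inheritParams run_sensilla
#' @return A \code{"spike_record"} containing all six populations.
#' @export
run_model <- function(waveform, params, variant = make_variant("control"),
                      seed = NULL, sensitivity = diag(2)) {
  if (!is.null(seed)) set.seed(seed)
  orn <- run_sensilla(waveform, params, variant, seed = NULL,
                      sensitivity = sensitivity)
  al <- run_network(orn, params, variant, seed = NULL)
  out <- rbind(as.data.frame(orn), as.data.frame(al))
  spike_record(out, t_total = attr(orn, "t_total"), dt = attr(orn, "dt"),
               n_per_pop = c(attr(orn, "n_per_pop"), attr(al, "n_per_pop")))
}
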