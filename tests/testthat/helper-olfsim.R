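# Shared fixtures: small parameter sets and a pure-R reference simulator
# used as an independent oracle for the compiled integrator.

small_params <- function(n_orn = 2) {
  p <- default_params()
  p$layout$n_orn_per_type <- n_orn
  p
}

noiseless_params <- function(n_orn = 2) {
  p <- small_params(n_orn)
  p$transduction$r_noise <- 0
  p$al$pn$I_noise <- 0
  p$al$ln$I_noise <- 0
  p
}

# reference sensillum simulation built from the exported step functions;
# one sensillum (ORN a + ORN b), deterministic (no receptor noise)
reference_sensillum <- function(waveform, params, omega_nsi) {
  tr <- params$transduction
  orn <- params$orn
  dt <- waveform$dt
  n_t <- length(waveform$t)
  r <- c(transduction_steady_state(waveform$conc_a[1], tr),
         transduction_steady_state(waveform$conc_b[1], tr))
  st <- list(list(V = orn$V_rest, y = 0, refr = 0),
             list(V = orn$V_rest, y = 0, refr = 0))
  spikes <- list(numeric(0), numeric(0))
  for (i in seq_len(n_t)) {
    conc <- c(waveform$conc_a[i], waveform$conc_b[i])
    r_old <- r
    for (k in 1:2) r[k] <- step_transduction(r[k], conc[k], tr, dt)
    for (k in 1:2) {
      out <- step_orn(st[[k]], r[k], r_old[3 - k], orn, omega_nsi, dt)
      st[[k]] <- out$state
      if (out$spiked) spikes[[k]] <- c(spikes[[k]], (i - 1) * dt)
    }
  }
  spikes
}

# analytic interspike interval of a LIF with constant total conductance
lif_isi <- function(g_in, V_in, orn) {
  gtot <- orn$gl + g_in
  v_inf <- (orn$gl * orn$V_rest + g_in * V_in) / gtot
  tau_m <- orn$C / gtot
  orn$tau_ref + tau_m * log((v_inf - orn$V_rest) / (v_inf - orn$theta))
}

make_rate_trace <- function(t, rates, population = "PN_a") {
  structure(list(t = t, rates = rates, rate = colMeans(rates),
                 population = population, tau = 20),
            class = "rate_trace")
}
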