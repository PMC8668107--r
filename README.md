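# olfsim

Spiking-network simulation of the early *Drosophila* olfactory system,
built to ask what non-synaptic ("ephaptic") interactions (NSIs) between
olfactory receptor neurons co-housed in a sensillum are good for, and how
they compare with the classical mechanism of lateral inhibition in the
antennal lobe (AL).

The package is for computational neuroscientists and olfaction
researchers who want to rerun or extend the model's in-silico
experiments: concentration-ratio encoding in odorant mixtures,
interference between asynchronous odor pulses, encoding of plume
correlation (single vs. separate odor sources), and the effect of
ephaptic coupling on ORN dynamic range.

## The model

Two ORN types (a, b) are paired in 20 sensilla. Transduction is a single
binding equation for the bound-receptor fraction *r*:

    dr/dt = alpha_r * c^n * (1 - r) - beta_r * r

The spike generator is a leaky integrate-and-fire neuron with
spike-rate adaptation *y*:

    C dV/dt = gl (Vrest - V) + g_y y (V_K - V) + g_r (r + zeta) (Vrev' - V)

The ephaptic interaction shifts each neuron's receptor-current reversal
toward rest in proportion to its sensillum partner's receptor
activation:

    Vrev' = Vrev - omega_NSI * r_partner * (Vrev - Vrest)

Each ORN type projects to the 5 projection neurons (PNs) of its
glomerulus through saturating conductance-based synapses; 3 local
neurons (LNs) per glomerulus are excited by their PNs and inhibit the
PNs of the *other* glomerulus. Four circuit variants are compared:
`control` (no lateral interaction), `NSI` (omega_NSI = 0.6), `LN`
(AL inhibition only), and `mix` (both).

A naturalistic plume generator produces correlated pairs of
odor-concentration time series with power-law (exponent -3/2) whiff and
blank durations and the field-calibrated concentration distribution,
coupled through a Gaussian copula.

## Worked example

Encode a 3:1 odorant mixture with and without ephaptic coupling:

```r
library(olfsim)

params <- default_params()
stim <- make_triangles(1e-3, 3e-3, duration = 50, delay = 0, onset = 500)

rec <- run_model(stim, params, make_variant("NSI"), seed = 1)
print(rec)
#> spike_record: 1688 spikes over 1050 ms
#>   ORN_a: 20 neurons, 467 spikes (22.2 Hz mean)
#>   ORN_b: 20 neurons, 506 spikes (24.1 Hz mean)
#>   PN_a: 5 neurons, 177 spikes (33.7 Hz mean)
#>   PN_b: 5 neurons, 222 spikes (42.3 Hz mean)
#>   LN_a: 3 neurons, 144 spikes (45.7 Hz mean)
#>   LN_b: 3 neurons, 172 spikes (54.6 Hz mean)

pn_a <- max_activity(sdf(rec, "PN_a"), onset = 500)
pn_b <- max_activity(sdf(rec, "PN_b"), onset = 500)
pn_b / pn_a                          # R_PN = 2.09
encoding_error(pn_b / pn_a, 3)       # 0.032
```

The PN response ratio (2.09) under NSIs sits much closer to the true
concentration ratio (3) than the control circuit's, which saturates:

```r
rec0 <- run_model(stim, params, make_variant("control"), seed = 1)
# control: R_PN = 1.17, encoding error = 0.191
```

The ephaptic mechanism suppresses the weakly driven channel in
proportion to the strongly driven partner's activity, undoing the
ceiling effect of the sigmoidal PN transfer — a six-fold reduction of
the coding error in this example.

Higher-level drivers reproduce whole experiment families
(`experiment_ratio_encoding()`, `experiment_async_pulses()`,
`experiment_plume_correlation()`, `dynamic_range_scan()`,
`run_experiment()` for tidy CSV + manifest output), and
`inst/cli/olfsim.R` exposes them as a command line
(`simulate`, `plume-gen`, `analyze`, `experiment` subcommands).

See the methods vignette (`vignettes/olfsim-methods.Rmd`) for the model
equations, unit conventions, parameter-interpretation decisions, the
numerical scheme, and known limitations.

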