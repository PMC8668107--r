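---
title: "Model and methods: simulating non-synaptic interactions in the fly's early olfactory system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

In *Drosophila*, olfactory receptor neurons (ORNs) are co-housed in pairs
inside cuticular sensilla, and the paired neurons inhibit each other
without synapses — so-called ephaptic or non-synaptic interactions (NSIs).
The same computations usually attributed to lateral inhibition in the
antennal lobe (AL) — concentration-invariant mixture-ratio coding and
separating odor sources by plume structure — could in principle be
performed a synapse earlier, inside the sensillum. `olfsim` implements a
spiking-network model of the first two stages of the fly olfactory
pathway to compare four circuit variants: a **control** with no lateral
interaction of any kind, an **NSI** variant with ephaptic coupling only,
an **LN** variant with AL lateral inhibition only, and a **mix** variant
with both.

# Model structure

## Transduction

Each ORN's receptor pool is described by the bound fraction $r \in [0,1]$
obeying a single Hill-type binding equation

$$\dot r = \alpha_r\,c^{\,n}\,(1-r) \;-\; \beta_r\, r,$$

with concentration $c$ in liquid-dilution (v/v) proxy units. A constant
offset $c_0$ is added to the stimulus concentration and generates
spontaneous receptor activation (about $r = 0.13$ at rest), which in turn
produces spontaneous spiking of roughly 20 Hz in the default
configuration. The half-activation concentration solves
$\alpha_r c^n = \beta_r$, i.e. $c \approx 2\times10^{-3}$.

## ORN spike generator

The spike generator is a leaky integrate-and-fire neuron with
conductance-based spike-rate adaptation,

$$C\dot V = g_l(V_\mathrm{rest}-V) + g_y\,y\,(V_K - V)
          + g_r\,(r+\zeta_r)\,(V_\mathrm{rev}' - V),$$

where $y$ decays at rate $\beta_y$ and jumps by a fixed increment at each
spike, and $\zeta_r$ is receptor noise. The ephaptic interaction enters
through the partner neuron's receptor activation $r_2$, which pulls this
neuron's receptor-current reversal potential toward rest:

$$V_\mathrm{rev}' = V_\mathrm{rev} - \omega_\mathrm{NSI}\, r_2\,
(V_\mathrm{rev} - V_\mathrm{rest}), \qquad 0 \le \omega_\mathrm{NSI} \le 1.$$

The coupling is applied symmetrically in both neurons of a sensillum and
is instantaneous, reflecting its electrical nature. Twenty sensilla per
type are simulated with independent noise.

## Antennal lobe

ORNs of one type converge onto the five projection neurons (PNs) of their
glomerulus through saturating release variables (`step_synapse`): a
presynaptic spike increments the activation by $\alpha(1-\hat s)$ and the
activation decays with its synaptic time constant. PNs carry
spike-rate adaptation with an inhibitory reversal potential and white
current noise; local neurons (LNs, three per glomerulus) are identical
LIF units without adaptation, driven by the PNs of their own glomerulus,
and inhibit the PNs of the *other* glomerulus only. The LN$\to$PN release
jump $\alpha_\mathrm{LN}$ is the second lateral-interaction strength; the
control and NSI variants set it to zero.

# Parameter interpretation and deviations worth knowing about

The published parameter table mixes units and, taken verbatim, three of
its entries do not reproduce the response properties the same source
documents. This package treats every value as a magnitude in a single
internal unit system (mV, ms, µS, nF; currents in nA) and makes the
following interpretive choices, each forced by a documented behavior of
the model rather than by convenience:

* **Adaptation increment.** The tabulated $\alpha_y = 0.45$ kHz is a rate,
  but the adaptation equation needs a dimensionless per-spike jump. A jump
  of 0.45 silences an ORN after a single spike (equilibrium rate
  $\beta_y y^*/\alpha_y \approx 3$ Hz), flatly contradicting the
  documented step response (a strong transient peaking tens of
  milliseconds after onset that decays to a dose-dependent plateau). The
  per-spike jump is therefore taken as the printed rate times the 0.1 ms
  calibration step, $\alpha_y = 0.045$, applied dt-independently. With it
  the step response peaks $\sim$30–50 ms after onset with plateau rates of
  30–70 Hz that grow with concentration.
* **Receptor noise.** Only the standard deviation ($r_\mathrm{noise} =
  0.5$) is given. Any *colored* noise of that amplitude rectifies through
  the receptor conductance into $\sim$40 Hz of spontaneous firing whose
  adaptation masks weak stimuli entirely. $\zeta_r$ is therefore white:
  an independent Gaussian per integration step with sd 0.5 at the 0.1 ms
  reference step, scaled by $1/\sqrt{dt}$ so its integrated effect is
  step-size invariant — the same convention the AL current-noise terms
  use.
* **ORN→PN conductance.** With sum-pooling over the 20 ORNs of a
  glomerulus, $g_\mathrm{ORN} = 0.6$ µS puts the PN transfer's half-max
  near 180 Hz of ORN population rate, outside the ORN operating range
  (0–110 Hz); PNs would barely respond and the weak component of any
  mixture would be thresholded out. The documented PN-versus-ORN transfer
  is a fixed-exponent sigmoid with half-max near 30–40 Hz; $g_\mathrm{ORN}
  = 1.0$ µS reproduces that anchor and is the default.
* **LN→PN conductance.** The tabulated 0.1 µS suppresses PN responses by
  only $\sim$4% — an LN variant indistinguishable from control. The model
  description prescribes a calibration instead: LN inhibition strength is
  chosen so the LN and NSI variants suppress the PN response to a
  synchronous pulse by the same amount. With $\omega_\mathrm{NSI} = 0.6$
  that calibration robustly gives $g_\mathrm{LN} = 0.8$ µS across all
  calibration concentrations tried (suppressions of 16–42% depending on
  concentration, always matching the NSI variant's).
* **$V_K$** (adaptation reversal) has no tabulated value; $-70$ mV, a
  typical potassium reversal, is the default and an explicit assumption.
* Reversal potentials printed with conductance units (and the LN noise
  printed in mV) are read as mV and nA respectively.

# Numerical scheme

Forward Euler at $dt = 0.1$ ms for all gating, adaptation and synaptic
variables, with per-spike jumps applied as instantaneous increments
(dt-independent). The ORN membrane is also integrated with forward Euler
(its total conductance keeps $g\,dt/C \lesssim 0.2$). The PN and LN
membranes are the exception: their leak conductances (10 and 6.2 µS on
1 nF) give membrane time constants of about 0.1 ms — equal to the step —
where plain Euler is unstable once synaptic conductance adds. Their
potentials therefore use the exact exponential relaxation toward the
instantaneous equilibrium $V_\infty$ over each step, which agrees with
Euler to first order and is unconditionally stable. Noise enters the
membrane as an additive Gaussian increment of sd
$I_\mathrm{noise}\sqrt{dt}/C$ per step. Halving $dt$ changes summary
statistics only within their trial-to-trial variability. All randomness
flows through R's RNG, so a seed makes full network runs bit-reproducible.

# Stimuli and the plume generator

Deterministic waveforms (steps, ramps, parabolas, and the triangular
pulses used as single-whiff surrogates) are generated on the integration
grid with a default 500 ms pre-stimulus settle period so adaptation
reaches its baseline.

Naturalistic plumes are alternating blanks and rectangular whiffs.
Whiff and blank durations follow a truncated power law with exponent
$-3/2$ (defaults: 0.03–50 s, the blank bounds equal to the whiff bounds),
and whiff concentrations follow the fitted piecewise distribution of the
normalized concentration $x = C/\langle C\rangle$:
$F(x) = \tfrac53 x$ for $x \le 0.3$ and $1 - 10^{-(a_1 + b_1 x)}$ above,
with $a_1 = 0.22$, $b_1 = 0.26$. The two branches disagree by about 0.3%
in probability at $x = 0.3$; the piecewise form is applied verbatim, so
the quantile function has a small jump at $u = 0.5$. One concentration is
drawn per whiff (rectangular whiffs; the within-whiff profile is not
specified by the source material and a constant is the simplest choice).
Concentration draws are scaled by the target mean whiff concentration
divided by the analytic mean of $x$ ($\approx 1.07$), so the expected
whiff concentration equals `mean_conc` (default $1.5\times10^{-3}$,
mid-range of the pulse experiments).

Correlation between the two odorant channels is imposed by a Gaussian
copula applied pairwise to the three draw streams (whiff durations, blank
durations, concentrations). Whiff alignment then *emerges* from the
cumulative durations: at $\rho = 1$ the channels are identical, while for
intermediate $\rho$ the channels' event clocks decohere after a few
cycles, so realized series correlation (and whiff overlap) is strongly
compressed toward zero until $\rho$ approaches 1. The package therefore
always reports the post-hoc realized correlation
(`measure_plume_stats`), and analyses of correlation encoding should be
read against it. Intermittency and mean concentration are invariant
across the correlation parameter by construction.

The realized whiff-duration tail is estimated with a truncation-aware
maximum-likelihood fit (`fit_powerlaw_exponent`), excluding whiffs cut by
the series boundaries.

# Read-out measures

Firing rates are spike-density functions: each spike contributes an
alpha-function kernel $\hat t\,e^{-\hat t/\tau}/\tau^2$ with $\tau=20$ ms,
shifted so the kernel starts rising one $\tau$ before the spike and peaks
at the spike time, normalized to unit area. (The source's printed kernel
has a positive exponent, which diverges; the standard alpha function is
the evident intent.) Per-neuron traces are averaged over the population.

*Maximum* and *average* activity are the per-neuron maximum (resp. mean)
within 200 ms of stimulus onset, averaged over the glomerulus. For
asynchronous pulses each glomerulus's window is anchored at its own
channel's onset, so the ratio $R_\mathrm{PN} = \nu_b/\nu_a$ is meaningful
at delays longer than the window. *Peak activity* integrates the rate
over epochs above a threshold (50/100/150 Hz) and is reported as a
supra-threshold spike count.

The coding error for a concentration ratio $R_\mathrm{conc}$ is
$\mathrm{err} = ((R_\mathrm{PN}-R_\mathrm{conc})/(R_\mathrm{PN}+R_\mathrm{conc}))^2$.
Correlation between $R_\mathrm{conc}$ and $R_\mathrm{PN}$ uses Pearson's
coefficient by default (Spearman available) — the estimator is not named
by the source.

Dose-response thresholds subtract the spontaneous baseline (the response
at the lowest concentration of the grid), then take the first
concentration reaching 10% ($C_l$) and 90% ($C_h$) of the maximum, with
log-linear interpolation; the first-crossing rule keeps both defined for
non-monotonic (peak-and-plateau) curves. Dynamic range is
$\log_{10}(C_h/C_l)$ and the sensitivity distance of a co-housed pair is
$\log_{10}(C_l^b/C_l^a)$.

# Experiment protocols and problem sizes

The packaged experiments use these default conditions, chosen once:

* **Step/ramp characterization** — 500 ms step at $2\times10^{-3}$ and a
  2 s ramp reaching $2\times10^{-3}$, 10 trials, 20 sensilla.
* **Ratio encoding** — synchronous 50 ms triangles, ratio grid
  $\{1,2,3,5,7,10\}$, six weak-odorant concentrations log-spaced from
  $2\times10^{-4}$ to $5\times10^{-3}$ (the source flags
  $\ge 5\times10^{-3}$ as very high), 10 trials. The four variants run on
  seed-matched noise, and control/LN share ORN simulations with NSI/mix
  as the circuit implies. The variant ordering of the mean coding error
  (mix $\le$ NSI $\le$ LN $\le$ control) is sharpest at upper-mid weak
  concentrations (around $4\times10^{-3}$), where the control PN response
  saturates; at low concentrations the ephaptic variants over-suppress
  the weak channel and the ordering inverts.
* **Asynchronous pulses** — equal 50 ms triangles at $10^{-3}$, delays
  $\{0,50,100,200,500\}$ ms. The LN variant suppresses the delayed
  channel most strongly at 100 ms delay and recovers by 500 ms
  ($\tau_\mathrm{LN} = 250$ ms); a 25 ms $\tau_\mathrm{LN}$ makes it
  behave like the NSI variant.
* **Plume correlation** — 50 s plumes (scaled down from 200 s for
  turnaround; the statistics at 50 s are already stable to within a few
  percent), maximum whiff duration 3 s, five plume realizations per
  correlation. Because plume realizations have heavy-tailed whiff
  durations, variant effects are assessed on seed-matched differences
  against control.
* **Dynamic range** — 50 ms triangles on one odorant driving both ORNs of
  a sensillum through a sensitivity matrix; concentration grids log-spaced
  over 4–5 decades, extended to $10^0$ for large sensitivity distances so
  the less sensitive neuron is recruited.

# What the synthetic stimuli do and do not show

The generator reproduces the marginal statistics of field-measured plumes
(duration power laws, concentration distribution, intermittency) but not
fluid dynamics: no advection, no spatial structure, no within-whiff
concentration profile, and channel alignment at intermediate correlation
decoheres rather than tracking a physical source separation. Passing
tests therefore validate the circuit-level comparisons between variants
under matched statistics; they do not validate predictions about real
plume geometry. Likewise the odor-delivery dynamics of laboratory
stimulation hardware are idealized as exact waveforms.

# Known limitations

* The ramp response retains a slow upward drift throughout the ramp
  (the sustained adaptation-balanced component tracks the rising
  receptor occupancy), so "time to plateau" depends on the stringency of
  the plateau criterion; a 5%-of-peak-slope rule is first met only near
  the ramp's end even though most of the rise completes within
  $\sim$200 ms.
* With the calibrated LN strength, LN suppression of a delayed pulse is
  clear at 100 ms delay (median $R_\mathrm{PN} \approx 0.87$–0.89) but
  shallower at 200 ms ($\approx 0.93$).
* Intermediate plume correlations compress toward zero realized
  correlation (above); correlation-encoding distances are therefore
  driven mainly by the ends of the correlation axis.
* Two glomeruli, one LN type, symmetric NSIs: the stated scope of the
  model, not incidental simplifications.
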