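---
title: "Dopamine-modulated working memory, criticality, and E/I balance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dopamine-modulated working memory, criticality, and E/I balance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcwm)
```

## The model

`pfcwm` simulates a recurrent spiking network in the tradition of
synaptic-facilitation models of prefrontal working memory.  The
excitatory pool (`N_E = 8000` by default) is divided into `p = 5`
item-selective populations of `f * N_E = 800` neurons each plus a
non-selective remainder; `N_I = 2000` inhibitory neurons provide global
feedback.  Every ordered pair of neurons is connected independently with
probability `c = 0.2`.  Excitatory-to-excitatory synapses within a
selective population are potentiated (`J_p = 0.45` mV), those between
different selective populations take the baseline value (`J_b = 0.10`
mV), and synapses touching the non-selective pool are potentiated with
probability `gamma = 0.1`.  The remaining classes are static:
`J_EI = 0.135`, `J_IE = 0.25`, `J_II = 0.20` mV (inhibitory deposits
applied with negative sign).

Membrane dynamics are leaky integrate-and-fire:

$$\tau_m \dot V_i = -V_i + I^{rec}_i(t) + I^{ext}_i(t),$$

with threshold 20 mV, reset 16 mV (E) / 13 mV (I), membrane constants
15 ms (E) / 10 ms (I), and a 2 ms absolute refractory period.  Recurrent
input arrives as delayed delta pulses: a presynaptic spike at time $t$
deposits an instantaneous potential jump $\hat J_{ij}$ on the
postsynaptic membrane after a synapse-specific delay drawn uniformly on
(0, 1] ms (quantized up to the 0.1 ms integration grid, so causality is
strict).

All E-to-E synapses express presynaptic short-term plasticity.  Each
excitatory neuron $j$ carries one utilization/resource pair $(u_j, x_j)$
shared by its outgoing E-to-E synapses:

$$\dot u_j = \frac{U - u_j}{\tau_u} + U\,(1-u_j)\sum_k \delta(t - t_k^{(j)}),
\qquad
\dot x_j = \frac{X - x_j}{\tau_x} - u_j\,x_j \sum_k \delta(t - t_k^{(j)}),$$

with `U = 0.2`, `X = 1`, `tau_u = 1500` ms (facilitation, slow) and
`tau_x = 200` ms (depression, fast).  On a spike the utilization jumps
first, the transmitted efficacy uses the post-jump $u$ and pre-jump $x$
($\hat J = J\,u^+ x$), then resources are consumed ($x \leftarrow x -
u^+ x$).  Facilitation outlasting depression is what lets a recently
active population keep an elevated effective coupling — the synaptic
trace that underlies loading and reactivating memory items.

Two printed-source ambiguities are resolved the standard way for this
model family: the recovery time constants are paired as above (the
facilitation constant must be the long one for working memory to
function), and the resource equation's spike term is consumption
(negative), since resources deplete with use.

### External drive and the noise convention

Each neuron receives Gaussian white-noise drive with mean `mu_ext`
(23.8 mV for E, 21.0 mV for I) and amplitude `sigma_ext = 1` mV.  We
adopt the white-noise-*current* convention of the model lineage this
network belongs to,

$$\tau_m \dot V = -V + \mu + \sigma\sqrt{\tau_m}\,\eta(t),$$

whose forward-Euler form is
$V \mathrel{+}= \frac{dt}{\tau}(\mu - V) + \sigma\sqrt{dt/\tau}\,\xi$
with $\xi \sim \mathcal N(0,1)$; the stationary free-membrane SD is then
$\sigma/\sqrt 2$, independent of $dt$.  The alternative convention
(stationary SD exactly $\sigma$) makes the resting network so
fluctuation-driven that the avalanche regime analyzed below (bin width
two times the population inter-spike interval, i.e. an event every
~0.15 ms in the analyzed population) is never reached; under the
adopted convention the bin-width rule and the network's operating point
are mutually consistent.  Memory stimuli multiply the target
population's `mu_ext` by a contrast factor `A_cue` (1.10 or 1.15) and
leave `sigma_ext` untouched.

Integration is forward Euler at `dt = 0.1` ms — delta synapses make
higher-order schemes pointless.  Deposits arriving while a neuron is
refractory are discarded and the membrane is clamped to the reset
potential.  Initial potentials are uniform on `[V_r, theta)`; every
analysis discards a 200 ms burn-in.  A reproducibility contract holds
throughout: every stochastic function requires an integer seed and
identical inputs + seed give bit-identical output (the engine carries
its own xoshiro256++/ziggurat generator, so streams do not depend on
the C++ standard library).

## Dopamine modulation

A D1 activation level $D \in [0, 2]$ scales all E-to-E efficacies by
$A_{EE}(D)$ and the E-to-I efficacy by $A_{EI}(D)$ (I-to-E and I-to-I
are never scaled).  Both factors are sigmoids with shared steepness
`K_c` but centres shifted to $D_0 - D_V$ (EE) and $D_0 + D_V$ (EI):
excitatory drive strengthens and saturates earlier than inhibitory
drive.  After normalization (the sigmoid term evaluated at $D = D_0$
with $D_V = 0$) the factor difference $\Delta A = A_{EE} - A_{EI}$ is
symmetric about, and maximal exactly at, the optimal level $D_0 = 1$:

```{r}
tr <- build_trajectory(da_params(), grid_step = 0.01)
tr$D[which.max(tr$dA)]
```

The factor *range* `[A_min, A_max]` is not a printed constant of the
source model; it decides where the dopamine trajectory sits in the
EE-EI plane and is treated as a calibration of the study conditions.
`calibrate_da_range()` implements the stated objective — maximal
loading sensitivity without spontaneous "imaginary memory" — by
bisecting the modulation depth until the resting state at $D_0$ sits
just on the quiescent side of the phase-transition border (majority
over seeds, 2000 ms probes), then backing off by a small margin.  The
frozen default in `da_params()` is the result of running this
calibration once on the full-size reference network.  The same
machinery can re-derive a range for any other network size.

## Phases, avalanches, and the criticality analysis

In the EE-EI plane the resting network shows a transition from a
quiescent regime (*phase1*, sparse noise-driven firing well below 2 Hz
per neuron) to a regime with self-sustained reverberation of one
selective population (*phase2*).  The transition is not sharp: a
*marginal reverberation band* borders it, in which one population
fluctuates in and out of a weak attractor at roughly 8-12 Hz.
`classify_phase()` therefore declares phase2 when any sliding 500 ms
window of the evaluation epoch sustains at least 12 Hz (boundary
inclusive): brief fluctuation peaks of the marginal band do not fill
half a second above that rate, while the separated self-sustained
regime does.  The calibrated dopamine trajectory places the optimal
activation level inside the marginal band, just on the quiescent side
of the sustained regime - which is also where the avalanche statistics
below are collected, consistent with a bin-width rule (twice the
population inter-event interval, about 0.3 ms) that presupposes a
semi-active analyzed population.  Working memory is the
stimulus-driven version of the same crossing: a loaded item is a
selective population pushed into the reverberating state that persists
after stimulus offset.  Near the border both ignition and early
survival of the attractor are probabilistic, so loading success at a
fixed duration is a probability, not a certainty; all protocol
measurements aggregate over seeds.

Avalanches are detected by binning one population's spike times at
`dt_bin = 0.3` ms (twice the population inter-event interval of the
reference resting runs; an adaptive mode recomputes `2 * mean ISI` from
the data): maximal runs of consecutive non-empty bins form avalanches,
sizes are spike counts, and sums of sizes conserve the total spike
count by construction.  The branching parameter is the arithmetic mean
over avalanches of (second-bin count)/(first-bin count), single-bin
avalanches contributing 0 (a configurable choice; the estimator is
validated on Galton-Watson fixtures with known offspring mean).

The size-distribution exponent is estimated in three stages: the
empirical density is smoothed by logarithmic binning (10 bins per
decade) with geometric-mean bin centres; candidate fit ranges spanning
at least one decade are scored by the Kolmogorov–Smirnov distance
between the in-range data and the *discrete* power law normalized on
the range's integer support; the least-squares slope of the smoothed
density over the KS-optimal range is the exponent.  Candidate ranges
are anchored at the smallest observed size by default, searching only
the upper cutoff: a free two-sided search (kept as `anchor = "free"`)
can lock onto a local shoulder of a distribution that is not a power
law at all, returning a seed-unstable slope of a fragment rather than
the body of the distribution.  The fitter is validated by recovering
known exponents from an independent inverse-CDF discrete sampler.

## Working-memory protocols

`wm_trial()` runs the loading/updating experiment: burn-in, a contrast
stimulus of given duration to one selective population, and a 1000 ms
post-offset epoch.  *Loaded* means the target keeps at least
`load_rate` in every sliding 100 ms window from 200 ms after offset to
the trial end; *updated* additionally requires the previously active
population to fall below `off_rate` over the final 300 ms.  The
defaults (5 Hz and 3 Hz) sit between the quiescent rate (well under
2 Hz) and the reverberating attractor's emergent rate (~8–11 Hz with
transient dips); the value 10 Hz sometimes quoted for such criteria is
unusable here because the attractor itself fluctuates around it.

`measure_t_sens()` finds the minimal loading duration `T_sens` (WM
sensitivity is `1/T_sens`).  Success at a probe duration is decided by
majority over 3 seeds.  Because an overlong stimulus depletes
presynaptic resources and the trace can collapse at offset, success is
*not* monotone in duration; the search therefore doubles the probe
duration from 1 ms until the first success and then bisects the
monotone low region (1 ms resolution).  `measure_t_flexi()` applies the
same machinery to overwriting a previously loaded item; its normalized
form (divided by the grid minimum, so the minimum is exactly 1) gives
WM flexibility as the reciprocal.  `wm_state_metrics()` reports the
stimulated population's firing rate `f`, mean utilization `u`, mean
resources `x`, transmitter per spike `ux`, and transmitter turnover
`uxf`, each with across-neuron SDs.

## E/I balance

Per-neuron input currents are recorded in four channels (recurrent
excitation, recurrent inhibition, external, leak), bin-summed at 5 ms.
`population_balance()` correlates excitatory against inhibitory traces
per neuron and reports |rho| (the printed variance-sum variant of the
correlation formula is available for audit but is not a correlation
coefficient).  In the `"total"` variant the excitatory channel is
recurrent excitation + external drive and the inhibitory channel is
recurrent inhibition + leak (the leak can be excluded); the
`"recurrent_only"` variant uses the two recurrent channels alone.  No
lag correction is applied: synaptic delays are below one current bin.
`isi_cv()` gives the coefficient of variation (sd/mean) of the pooled
inter-spike-interval distribution, validated against renewal-process
closed forms (periodic 0, exponential 1, Gamma(k) $1/\sqrt k$).  For
the dopamine dose-response of spiking irregularity the intervals are
pooled across the whole excitatory pool of a resting run: the
irregularity signature of near-criticality lives in the cross-
population burst structure, which a single population's intervals
undersample.  For the current-correlation dose-response a 500 ms
stimulus is used so each neuron contributes a 100-bin trace, long
enough for stable per-neuron correlation estimates.

## Synthetic fixtures

Every analysis operation has an independent ground-truth generator that
shares no numerical code with the estimator it tests: Galton–Watson
rasters with known offspring mean (branching parameter), an inverse-CDF
discrete power-law sampler (exponent fitting), Gaussian pairs with
known mixing correlation (balance), and renewal trains with known
interval laws (CV).  All are seed-reproducible.

## Problem sizes and what the tests show

The full Table-style network (10,000 neurons, ~2x10^7 synapses, 2000 ms
at 0.1 ms) simulates in a few seconds per run in the compiled engine;
the criticality protocol averages 15 independent
connectivity/simulation seeds per dopamine level.  The test suite
exercises the full-size network only sparsely and otherwise uses an
in-degree-preserving reduction (`scale_network(spec, 4)`: 2,500
neurons, `c = 0.8`) or purpose-built micro-networks; the acceptance
script re-runs the full protocol.  Synthetic-data tests tell us the
estimators recover known ground truth at stated tolerances; network
tests tell us the model reproduces the joint pattern — maximal WM
sensitivity, avalanche exponent nearest -1.5, branching parameter
nearest 1, maximal E/I correlation and ISI CV, all at intermediate D1
activation.  They do not, of course, establish anything about
biological tissue: the generator emulates the model's own study
conditions (homogeneous random connectivity, Gaussian drive, delta
synapses), not features of real recordings such as conductance
synapses, spatial structure, or non-stationary neuromodulation.

## Known limitations

- The phase border is stochastic; the calibrated `[A_min, A_max]` is a
  frozen draw of a majority-vote bisection, not a sharp constant.
- Near the border, loading success is probabilistic; `T_sens` inherits
  majority-vote noise of a few ms.
- The avalanche exponent describes the distribution body up to a
  KS-chosen cutoff; it is not a tail MLE, and on non-power-law inputs
  the two disagree by design.
- Currents are recorded only for neurons requested via
  `record_currents` (memory), and refractory periods discard incoming
  deposits rather than accumulating them.
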