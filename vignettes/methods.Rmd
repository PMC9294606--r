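---
title: "Models and measurement rules in synapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement rules in synapkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapkit)
```

synapkit analyses two sides of inhibitory synaptic physiology in
whole-cell patch-clamp recordings: transmission (evoked and miniature
inhibitory postsynaptic currents, IPSCs) and excitability (action
potential waveforms and firing). This vignette explains the models, the
measurement rules, the choices that were genuinely open, and what the
synthetic-data generators do and do not emulate.

## The vesicle depletion model

The core model treats a synapse (or a population of synapses recruited
by one extracellular stimulus) as a single readily releasable pool. At
stimulus $k$ the pool holds $N_k$ vesicles; a fraction $P_r$ is
released, each contributing a quantal amplitude $Q$ to the postsynaptic
current:

$$A_k = N_k \, P_r \, Q,$$

and the pool is refilled at a constant rate $\rho$ (vesicles/s)
throughout the train:

$$N_{k+1} = N_k - P_r N_k + \rho\,\Delta t_k .$$

Whether replenishment is delivered continuously or once per interval is
indistinguishable in this discrete recursion — the increment over an
interval is $\rho \Delta t$ either way — so the integrated form is used.
For a regular inter-stimulus interval the normalized amplitude has the
closed form

$$\frac{A_k}{A_1} = \frac{r}{p} + \Bigl(1 - \frac{r}{p}\Bigr)(1-p)^{k-1},
\qquad r = \frac{\rho\,\mathrm{ISI}}{N_1},$$

which relaxes geometrically to the fixed point $r/p$. This closed form
(`closed_form_train()`) is kept as an independent oracle for the
simulator and agrees with it to machine precision.

Stochastic mode replaces the expected release with a binomial draw,
$\mathrm{rel}_k \sim \mathrm{Bin}(\mathrm{round}(N_k), P_r)$, while
replenishment stays deterministic — the simplest stochastic extension
consistent with the model above. The pool is not capped during trains
(the linear-replenishment reading of the recursion) but is capped at
$N_1$ during recovery simulations, where a refilled pool larger than its
resting size would be unphysical and recovery ratios must saturate at 1.
Both behaviours are exposed as a flag.

## Estimating Pr, pool size and replenishment from trains

Both cumulative-IPSC estimators operate on amplitudes normalized to the
first response, which removes differences in the number of axons
recruited by stimulation.

**Train method.** Cumulative normalized amplitude is plotted against
stimulus number and an ordinary least-squares line is fitted to the late
portion of a 40-stimulus, 100 Hz train. The y-intercept estimates the
relative readily releasable pool, its reciprocal estimates $P_r$ (the
first response being 1), and the slope is proportional to the
replenishment rate (at the fixed point it equals $r/p$ exactly). The
conventional description of the late fit window ("last 7 points,
stimuli 33–40") is internally inconsistent — 33–40 is eight stimuli —
so the default fit range is the full 33:40 (eight points), and the range
is configurable.

**Elmqvist–Quastel (EQ) method.** Each of the first five normalized
amplitudes is plotted against the cumulative amplitude of the
*preceding* responses and fitted with a line; the x-intercept estimates
the relative pool, and $P_r$ = first amplitude / x-intercept. For a
zero-replenishment geometric train the relation
$A_k = 1 - p\,\mathrm{cum}_{k-1}$ is exactly linear, so the estimator is
exact for every $p$ — the basis of the package's exactness tests. The
x-intercept is provably identical under the inclusive cumulative
convention, which we verified numerically; the exclusive convention is
used. A transposed phrasing of the $P_r$ rule sometimes seen
("x-intercept divided by the first amplitude") would return the pool
size itself; the reciprocal form used here is consistent with the Train
method.

Two quantitative caveats, both asserted (and deliberately left failing
where stated) in the test suite:

- The EQ estimate is *not* replenishment-independent at physiological
  replenishment strengths. With $p = 0.2$ and a cumulative slope of 0.2,
  reducing replenishment by 35% shifts the deterministic EQ $P_r$ by
  about 11% (0.151 to 0.167). This mirrors the behaviour of real
  estimates at such synapses, where the EQ $P_r$ reads slightly higher
  when replenishment is lower, and means EQ shifts below ~10% should not
  be over-interpreted as release-probability changes.
- Under binomial noise (pool 100, 10-sweep averages), the median
  recovered $P_r$ carries a small positive bias from the nonlinear
  $1/x$-intercept transform; at $p = 0.1$ it is ~12%, shrinking to a
  few percent by $p = 0.2$ and vanishing for larger pools. The
  deterministic estimators are exact, so this is a sampling property,
  not an implementation error.

## Amplitude measurement under summation

During 100 Hz trains each IPSC rides on the decaying tail of its
predecessors. Amplitudes are measured per stimulus as the extremum in a
0.5–8 ms post-stimulus window minus a local baseline. The baseline is a
straight line fitted to the 1 ms immediately before the stimulus and
extrapolated under the response window: a flat pre-stimulus mean
systematically underestimates late amplitudes (by ~16% when the slow
decay constant is five times the inter-stimulus interval, because the
tail keeps decaying under the response), while the sloping baseline
tracks the tail to within ~2.5% even in that stress case.

## Synthetic recordings and ground truth

All generators are pure functions of (parameters, seed) and return the
exact ground truth used to score the analyses.

- **Kernel**: unitary PSC waveform
  $(1 - e^{-t/\tau_r}) (w e^{-t/\tau_f} + (1-w) e^{-t/\tau_s})$,
  peak-normalized. Defaults are wild-type-like miniature-IPSC kinetics
  ($\tau_f$ 6.25 ms, $\tau_s$ 13.4 ms, $w$ 0.7, $\tau_r$ 0.7 ms); $w$ is
  a package choice since only the time constants are reported for real
  events.
- **Miniature events**: homogeneous Poisson times, log-normal amplitudes
  (strictly positive and right-skewed, as empirical mini distributions
  are; CV 0.3 by default since only means are reported), linear
  summation, additive Gaussian noise band-limited to 5 kHz — the
  low-pass corner of a typical acquisition chain — and rescaled to the
  requested SD. The default noise gives a peak SNR of 5 at the
  wild-type mean amplitude (57.4 pA).
- **Evoked trains**: per-sweep amplitude series from the depletion
  model, rendered as scaled kernels with linear summation plus noise.
- **Action potentials**: piecewise-linear templates whose threshold,
  amplitude, half-width, maximal slopes and AHP depth equal the
  requested values *by construction* (a flat apex sized so the
  half-amplitude width is exact; a three-sample flat trough so the
  sampled AHP minimum is exact). Spike times in step sweeps come from a
  leaky-integrator scheduler with closed-form first-spike latency
  $t = -\tau_m \ln(1 - \Delta V / (I R_m))$; the rendered subthreshold
  path between crossings is linearised, which is analysed only for
  spike detection, never for waveform features. Templates are analytic
  constructions, not conductance-based simulations: the measurement
  surface being validated is feature extraction, so exactness of the
  ground truth matters more than biophysical realism.

What the generators do **not** emulate: stimulus artifacts (an optional
stress feature was considered and deliberately omitted — the detector
windows never include the stimulus time), access-resistance errors,
baseline drift, event-kinetics heterogeneity across synapse populations,
and conductance-driven spike-shape variability. Passing tests therefore
demonstrate correctness of the measurement rules under linear summation
and stationary band-limited noise, not robustness to every artifact of
real recordings.

## Miniature-event detection

The detector is a scaled-template matcher: at every lag the kernel
template is fitted with free scale and offset, and the detection
criterion is the fitted scale divided by its standard error; criterion
local maxima above threshold (3.5 by default) mark events, separated by
a 1 ms refractory window. The free offset is what keeps the method
usable at ~80 Hz, where events ride on their predecessors' tails.
Three implementation decisions matter at high rates:

- **Short template** (3 ms default): windows spanning the full decay
  almost always contain several events at 80 Hz and destroy the
  criterion's specificity; a template covering the rise and early decay
  discriminates far better.
- **Matching at ~10 kHz** with full-rate refinement: the criterion is
  computed on a decimated trace for speed, then each event's time and
  amplitude are re-fitted on the raw 50 kHz trace at every sub-grid
  lag. On isolated noiseless events the refined times and amplitudes
  are exact.
- **Subtract-and-rescan with coordinate refits**: detected events are
  subtracted as fitted kernels and the residual is scanned once more,
  recovering events hidden under close neighbours; each event is then
  re-fitted against the trace with all others removed (two
  coordinate-descent sweeps), and the rescan applies a stricter
  criterion (default +1.5) because it operates on a noise-dominated
  residual.

At the wild-type study conditions (78.1 Hz, SNR 5) this reaches ~92%
recall and ~95% precision. The residual undercount is structural: with
a 1 ms refractory, about 7.5% of Poisson event pairs at 78 Hz arrive
closer than the minimum separation and are merged by *any*
refractory-honoring detector, so detected frequency reads a few percent
below the true rate. Detection thresholds and template settings are
package defaults declared here, not values inferred from any particular
acquisition software.

Event kinetics (amplitude, onset at the 5% crossing, interpolated
10–90% rise, biexponential decay fit by bounded Levenberg–Marquardt)
are measured on averaged events; the same routine serves slower
agonist-evoked currents. Pure mono-exponential decays make the
biexponential Jacobian singular, so the fit falls back to a
single-exponential model and flags the slow component unidentifiable.

## Action-potential features

Threshold is the membrane potential at the last upward crossing of
dV/dt = 20 mV/ms before the peak (the criterion is configurable and
reported; it is a package default, as is common when the acquisition
threshold rule is not stated). Crossings are refined to sub-sample
precision by interpolating dV/dt and intersecting the pre-onset and
rising slopes. Amplitude is peak minus threshold; half-width is the
interpolated width at threshold + amplitude/2; maximal rise and fall
rates are central-difference dV/dt extrema between threshold and the
AHP trough (no smoothing at 50 kHz); the fall rate is reported as a
positive magnitude. The AHP is measured from the *threshold* voltage to
the minimum within 10 ms after the peak — threshold-referenced rather
than baseline-referenced, the natural choice for fast AHPs, and flagged
in outputs since conventions differ. Evoked firing rate is spike count
over step duration (robust at low counts; the reciprocal-ISI
alternative is deliberately not the default). Input resistance is the
origin-constrained least-squares slope of steady-state voltage
deflection against injected current.

## Statistics and the pipeline

Group comparisons use two-tailed unpaired Student's t-tests (pooled
variance) by default, with Welch's variant behind a flag and no
multiple-testing correction — matching common practice in this
literature even where Welch would be preferable; the choice is
deliberate and visible in every output row. `run_pipeline()` generates
synthetic cohorts for configured groups, runs all stages, and writes
per-cell tables, group statistics, plots and the fully resolved
configuration (including every default) so a run is auditable and
byte-reproducible from (config, seed). Per-cell estimates are computed
first and then compared across groups (fitting averaged curves instead
is possible by averaging sweeps before analysis).

## Problem sizes

The packaged defaults and test problem sizes are chosen so every
analysis validates in seconds to a couple of minutes on one CPU:
40-stimulus trains, 10-sweep averages, 10–60 s miniature recordings at
50 kHz, 50-seed recovery suites. These are the same orders of magnitude
as the corresponding experiments; only the miniature-trace durations
used in unit tests (10–20 s) are shorter than a typical 60 s recording,
which affects only the variance of the frequency estimates.
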