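---
title: "From current-clamp sweeps to group statistics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From current-clamp sweeps to group statistics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahpkit)
```

## The problem

Pyramidal neurons respond to a sustained depolarizing current step with an
accommodating spike train, and when the step ends the membrane potential
undershoots the baseline: the after-hyperpolarization (AHP). The AHP is a
mixture of a *medium* component that decays within a few hundred
milliseconds and a *slow* component (sAHP) that decays over seconds and is
carried by calcium-dependent potassium currents. Stress hormones such as
corticosterone modulate the sAHP selectively in some brain regions, which
makes precise, automated separation of the two components - and honest
group-level statistics on the separated amplitudes - the methodological
heart of this kind of study.

`sahpkit` implements that trace-to-statistics pipeline end to end:

1. passive membrane properties from a small hyperpolarizing probe step;
2. spike detection and single-spike waveform features;
3. constrained bi-exponential decomposition of the post-step AHP;
4. two-group mixed-effects inference with influence screening, multiple
   imputation, and simulation-based power analysis.

Because raw recordings of this kind are rarely deposited, the package
includes a synthetic-sweep generator with exact ground truth; every stage
is validated against it.

## The sweep and its forward model

A sweep lasts 8.2 s at a default 50 kHz: a 100-ms baseline, a -20 pA /
200 ms hyperpolarizing probe, a recovery gap, a 600-ms depolarizing step
(one of 150-450 pA in 25-pA increments, 13 sweeps per cell), a long
post-step window for the AHP, and a 200-ms zero-current segment at the end
used to read the resting potential. Synthetic cells rest at the target
baseline (default -70 mV), so the generator's holding current is zero; in
real recordings the holding current only exists to position the cell there.

The generator's forward model is the superposition the analysis inverts:

* **Passive probe response.** The probe charges the membrane as
  $V(t) = V_{\mathrm{off}} + I\,[R_a(1 - e^{-t/\tau_p}) + R_{in}(1 - e^{-t/\tau_m})]$,
  a fast series/pipette component and a slow membrane component. Defaults
  ($R_{in}$ = 230 M$\Omega$, $\tau_m$ = 30 ms, $R_a$ = 30 M$\Omega$,
  $\tau_p$ = 1 ms) sit at typical hippocampal pyramidal values.
* **Subthreshold envelope during the spiking step.** A real neuron does not
  charge to $I R_{in}$ under a 300-pA drive; spiking clamps the inter-spike
  potential near threshold. The generator therefore charges the envelope
  (5-ms effective time constant under strong drive) toward the spike
  threshold, capped there. This is a realism decision with a testing
  payoff: the envelope stays below the +40 mV spike-detection criterion, so
  detection ground truth is exact.
* **Spikes.** Stereotyped difference-of-exponentials templates (rise 0.15
  ms, fall 1.0 ms, peak 80 mV above rest) placed at generated onset times;
  interspike intervals are geometrically stretched so that the last/first
  ISI ratio equals the `isi_adaptation` parameter. No conductance model is
  used - the pipeline under test needs realistic geometry (threshold kink,
  >40 mV height, ~1 ms half-width), not biophysics - and templates keep
  the ground truth exact. The last spike ends at least 20 ms before the
  step offset, so spike waveforms never contaminate the AHP window.
* **AHP tail.** From the first sample after the step offset the trace is
  exactly baseline plus
  $V_{med}e^{-t/\tau_{med}} + V_{slow}e^{-t/\tau_{slow}}$. The passive
  discharge of the depolarizing envelope is window-limited (it ends at the
  offset) rather than superposed into the tail: during spiking the AHP
  conductances dominate repolarization anyway, the fitted model treats the
  tail as a pure bi-exponential, and this choice keeps the tail's ground
  truth exact. The price is a stylized cliff at the offset, which the
  analysis never looks at.
* **Noise.** White Gaussian noise brick-wall low-passed (zero phase, FFT)
  at 2 kHz, matching a 0-2 kHz acquisition bandwidth, then rescaled so its
  delivered standard deviation equals `noise_sd`. Recordings of this kind
  do not come with a published noise figure; the default 0.2 mV (a free
  realism parameter, plausible range 0.1-0.3 mV) makes single sweeps look
  right and is the condition under which all recovery properties are
  tested.

## Smoothing, spikes, and their numerical details

All feature extraction runs on traces smoothed by a centered local linear
least-squares fit over a 1-ms window (a degree-1 Savitzky-Golay filter).
Constants and ramps pass unchanged; a 1-ms window does flatten the spike
peak, so waveform features are defined *on the smoothed trace* for both the
implementation and its brute-force test oracle.

Spikes are local maxima exceeding the baseline (mean of the 100 ms before
the step) by more than 40 mV, with a 2-ms refractory separation - below any
physiological ISI, above noise peak spacing. The threshold is found by
scanning backward from the peak on the centered-difference dV/dt trace for
the start of the contiguous run above 20 mV/ms; scanning backward avoids
noise-triggered early crossings. Crossing times for the 20-80% rise time
and the half-width interpolate linearly between samples: at 50 kHz a 150-us
rise time spans only 8 samples, so sub-sample interpolation materially
reduces quantization error. With two spikes the first and last interval
coincide, so the accommodation index (100 x last ISI / first ISI) requires
at least three spikes and is reported missing otherwise. Both the absolute
peak potential and the threshold-to-peak amplitude are reported, because
the two conventions coexist in the literature; the group-comparison report
uses the latter.

## Passive fit

The probe-step model above is fitted by Nelder-Mead on the smoothed
segment. Three implementation details matter:

* **Smoothed-space fitting.** The 1-ms smoothing window biases a 1-ms
  exponential by several percent. The model prediction is therefore passed
  through the same smoothing operator as the data before the SSE is
  computed, which makes the estimator exactly unbiased for noiseless
  signals (the first/last half-windows, where edge fits differ, are kept
  out of the fit range).
* **Parameterization.** The search runs over transformed time constants
  ($\tau_p$ logistic onto (0, 10] ms; $\tau_m = \tau_p(1 + e^b)$ enforces
  ordering), with the offset and the two resistances profiled out by linear
  least squares at every step; a negative profiled $R_a$ is refit at zero.
  Three starts (method-of-moments seed from the 63% crossing, times two
  perturbations) plus a polish run guard against local minima;
  non-convergence is flagged, never raised.
* **Direct cross-check.** `direct_resistance_estimate()` avoids the model
  fit: total resistance from the steady-state deflection (with a small
  correction for residual membrane charge), membrane component from a
  log-linear regression of the charging deficit, series resistance as the
  remainder. Fit and direct estimate agree within a few percent whenever
  $\tau_p < \tau_m/10$ and the step reaches steady state - which is the
  regime in which the cross-check is meaningful.

Cells enter the group analysis only if their fitted input resistance lies
in [100, 450] M$\Omega$ - both ends inclusive, the conservative reading of
an inclusion interval - since values outside that window suggest the
recording was not from a pyramidal cell.

## AHP decomposition

The post-step decay is modeled from its peak as
$V(t) = V_{med}e^{-t/\tau_{med}} + V_{slow}e^{-t/\tau_{slow}}$ with
$\tau_{med} \in (0, 400]$ ms and $\tau_{slow} \in (400, 8000]$ ms, the
standard bracketing of medium versus slow AHP kinetics. Numerical choices:

* The peak is the most negative excursion relative to baseline within
  100 ms of the step offset, excluding a 2-ms guard right after the offset
  where the smoothing window straddles the discontinuity.
* The fit runs on the smoothed trace decimated to 1 kHz by *block
  averaging*. Block means are unbiased for decays this slow; an IIR
  anti-alias filter, by contrast, rings at the offset cliff and
  contaminates the early tail (the general-purpose [decimate_trace()] uses
  a zero-phase FFT low-pass instead, which preserves passband amplitudes
  exactly).
* Bounds are enforced inside Nelder-Mead by logistic transforms of each
  decay constant onto its interval; amplitudes stay unconstrained and are
  reported signed, negative-down. Initialization scores a 3 x 3 grid of
  decay pairs (50/150/350 ms x 1/3/6 s) with linear least-squares
  amplitudes, ties broken toward the smaller slow constant, and a second
  Nelder-Mead run polishes the first optimum.
* Components are labeled by the interval their decay constant occupies,
  never by amplitude order. A fit pinned at an interval edge is flagged
  `at_bound`; decay constants within a factor of two of each other are
  flagged `ill_conditioned`, because two exponentials that close are not
  separable - with both generative constants inside (300, 500) ms, most
  fits carry one of these flags, and the flags are the honest output.
* Goodness of fit is the squared Pearson correlation between fit and
  (smoothed, decimated) data over the fit window; amplitudes are referenced
  to the detected peak time, so a fitted amplitude is the component's value
  at the fit start, a few ms after the offset.

The ablation contrast averages fitted amplitudes over the 325-450 pA steps
before and after a simulated pharmacological block, mirroring the classic
Forskolin control in which the sAHP collapses while the mAHP is spared.

## Cohort statistics

The response for group inference is the fitted slow (or medium) amplitude,
one row per cell and step, missing rows flagged rather than dropped. The
mixed model is `response ~ group * step + (1 + step | cell)` with the
current step centered and rescaled (per 100 pA - random-slope variances of
order $10^{-6}$ in per-pA units are numerically hostile; coefficients are
reported on both scales). The step enters as a continuous covariate: the
study design calls current a 13-level factor, but reported interaction
tests carry a single degree of freedom, which only a linear trend
interaction produces; the 12-df factor coding remains available behind
`step_coding = "factor"`. Estimation is by maximum likelihood, not REML,
because likelihood-ratio tests compare fixed-effect structures; a singular
random-effect covariance triggers a flagged refit with the diagonal
structure.

**Influence.** Cook's distances are computed for the fixed effects after
whitening by the model-implied marginal covariance (block diagonal by
cell), where the ordinary case-deletion identity applies; the test suite
checks the closed form against brute-force leave-one-observation-out
refits. Observations above the 4/n cutoff are set missing and imputed
together with the genuinely missing ones - screening runs before
imputation.

**Imputation.** Missing responses are imputed under a multivariate-normal
model of the 13-step response vector per cell with group-specific means and
a pooled covariance, estimated by expectation-maximization; each of the m
imputations estimates the model on a bootstrap resample of cells (within
group), which is what propagates parameter uncertainty into the draws. The
covariance is shrunk toward its own diagonal with weight p/(n+p) (13
dimensions against a few dozen cells needs the regularization), with a
small variance floor for degenerate bootstrap resamples. The default m = 20
balances Monte-Carlo error against runtime; pooling uses the standard
combining rules for estimates and the standard multiple-imputation
chi-square combination (D2) for likelihood-ratio statistics, since the
pooled-versus-averaged choice is not dictated by the design.

**Correlation.** The sAHP-amplitude-versus-spike-count relation is
evaluated on per-step group means (13 points per group) - per-cell pairing
would mix within- and between-cell variation into a single coefficient.

**Power.** Power for the interaction is estimated by simulating cohorts at
each total cell count from an effect specification (from generator truth or
from a fitted model, optionally drawing the interaction slope from its
estimation uncertainty, the Monte-Carlo analogue of posterior sampling),
refitting the full and reduced models, and counting rejections. A
noncentral-chi-square closed form
($\lambda = \beta^2 / [(1/n_v + 1/n_t)(\sigma_b^2 + \sigma_e^2/S_{xx})]$)
serves as an asymptotic cross-check; at small per-group counts (N around
20) the simulation runs a few points below it, as expected of an
asymptotic approximation, and the agreement is tested at N of 40 and
above.

## Default cohort conditions

The default cohort is 20 vehicle and 15 treated cells - the cell counts of
a typical slice-incubation comparison - with a slow-AHP magnitude of 1.0 mV
at the 300-pA reference step growing by 0.004 mV/pA, a treated-group extra
growth (the interaction) of 0.0014 mV/pA, random intercept/slope standard
deviations of 0.3 mV and 0.001 mV/pA, residual 0.25 mV, and 3% of sweeps
missing completely at random. These values reproduce the qualitative
anatomy of the motivating experiments: a clearly significant interaction at
hippocampal-like effect size, an underpowered one at roughly half that
slope (0.0008 mV/pA), where 80% power requires on the order of 70 cells.
Medium-AHP amplitudes (3.5 mV at reference, same growth, no group effect)
match the scale at which the mAHP is reported unchanged. Outlier injection
(`outlier_frac`, displacement in residual-sd multiples) is off by default.
Missingness is MCAR; the corrupting mechanism in real recordings is not
specified beyond "random noise", and nothing in the pipeline depends on a
finer model.

The table-level arm of the generator (`simulate_response_table()`) draws
amplitudes without the non-negativity clip that trace synthesis applies, so
the statistical machinery is calibrated against an exactly linear mixed
model; the clip only matters for sweeps whose generative amplitude would be
positive, i.e. no AHP, which trace synthesis renders as such.

## Problem sizes used in validation

The test suite and the acceptance script trade sampling rate against what
each check needs: spike-feature checks run at the full 50 kHz (rise times
span only a handful of samples, which is the point), passive-fit recovery
at 20 kHz (the 1-ms series component still spans 20 samples), AHP-fit and
cohort-level runs at 2-10 kHz (the fit decimates to 1 kHz regardless).
Monte-Carlo sizes follow the property being tested: 100 seeds for
recovery distributions, 200 cohorts for estimator bias, 500 for type-I
calibration, 200-300 simulations per power-grid point.

## What passing tests do and do not show

The generator produces clean, stationary sweeps: no electrode drift, no
seal degradation, no line interference, no bridge-balance error, no
temperature trends, and spike shapes that do not change over the train.
Passing recovery tests therefore demonstrate that the *analysis* is
correct and well-calibrated under the stated noise model - not that real
recordings meet that model. On real data the QC filter, the convergence
and boundary flags, and the influence screen are the mechanisms that
surface model violations; they are exercised here only against synthetic
pathologies (constructed outliers, degenerate decay constants, corrupted
files).

Known limitations: the AHP model is strictly bi-exponential (no third
component, no conductance model); ablation controls are simulated, not
pharmacological; the imputation model assumes within-group multivariate
normality across steps; and vendor acquisition formats are out of scope -
data enter through the documented TSV + JSON container.
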