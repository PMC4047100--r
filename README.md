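# sahpkit

Trace-to-statistics analysis of the slow after-hyperpolarization (sAHP) in
current-clamp recordings from pyramidal neurons.

## The problem

After a depolarization-evoked spike train, a pyramidal neuron's membrane
potential undershoots its baseline. That after-hyperpolarization is the sum
of a **medium** component (decay < 400 ms) and a **slow** component (decay
0.4-8 s, carried by calcium-dependent potassium currents). Stress hormones
modulate the sAHP selectively in some brain regions, so experiments of this
kind record families of 13 sweeps per cell (600-ms depolarizing steps, 150
to 450 pA in 25-pA increments, responses recorded for 8 s at 50 kHz) in two
treatment groups, and need:

1. **passive membrane properties** from a -20 pA / 200 ms probe, by fitting
   `V(t) = V_off + I [R_a (1 - e^(-t/tau_p)) + R_in (1 - e^(-t/tau_m))]`
   (Nelder-Mead, on the smoothed trace), plus the 100-450 MOhm
   input-resistance inclusion filter;
2. **spike features**: detection (>40 mV above baseline), threshold (first
   sustained crossing of dV/dt = 20 mV/ms), 20-80% rise time, rising slope,
   width at half maximum, and the accommodation index
   (100 x last ISI / first ISI);
3. **AHP decomposition**: constrained bi-exponential fit of the post-step
   decay, `V(t) = V_med e^(-t/tau_med) + V_slow e^(-t/tau_slow)` with
   tau_med in (0, 400] ms and tau_slow in (400 ms, 8 s], components labeled
   by interval, goodness of fit as the squared Pearson correlation;
4. **group inference**: linear mixed-effects model
   `response ~ treatment * current + (1 + current | cell)` fitted by ML,
   likelihood-ratio tests, Cook's-distance influence screening at the 4/n
   cutoff, multiple imputation of missing/flagged observations by
   expectation-maximization with bootstrapping, pooled estimates and pooled
   LRT statistics, per-group correlation of sAHP amplitude with spike
   count, and simulation-based power for the treatment-by-current
   interaction.

No raw recordings ship with the package. A synthetic-sweep generator with
exact ground truth (`generate_trace()`, `generate_cohort()`) stands in for
them, and the entire validation suite measures the pipeline against that
ground truth.

## Worked example

```r
library(sahpkit)

# one synthetic sweep at 300 pA, and its AHP decomposition
tr <- generate_trace(current_protocol(300, sampling_rate = 10000),
                     trace_gen_params(seed = 1))
fit <- fit_ahp(tr)
round(unlist(fit[c("v_med", "tau_med", "v_slow", "tau_slow", "r2")]), 3)
#>    v_med  tau_med   v_slow tau_slow       r2
#>   -3.446  120.441   -1.393 6006.977    0.975

# full pipeline on a 20 + 15 cell cohort (simulate -> features -> QC -> stats)
res <- run_pipeline(pipeline_config(seed = 7, out_dir = "sahp_run",
                                    sampling_rate = 10000))
res$stats$lrt_interaction[c("chi_square", "p_value")]
#> $chi_square
#> [1] 16.22747
#> $p_value
#> [1] 0.0001540495
print(pipeline_report("sahp_run"))
```

The decomposition recovers the generative medium amplitude (-3.5 mV, 120
ms) and slow amplitude (-1.4 mV, 6 s); amplitudes are referenced to the
detected AHP peak a few ms after the step offset, hence -3.46 rather than
-3.50. The pooled interaction test rejects: the treated group's sAHP grows
faster with injected current than the vehicle group's, which is the
generative truth for the default cohort.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate + extract, group inference, ablation control, power),
writing their tables under `results/`.

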