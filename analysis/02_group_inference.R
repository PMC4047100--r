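#!/usr/bin/env Rscript
# Step 2: group-level inference on the extracted features. For the slow and
# the medium AHP amplitude: linear mixed-effects model (treatment x current
# interaction, per-cell random intercept and slope), Cook's-distance
# influence screen at 4/n, multiple imputation of missing and flagged
# observations, pooled likelihood-ratio tests, and the per-group
# correlation between sAHP amplitude and spike count. Reads results/run/,
# writes results/stats_v_slow.json and results/stats_v_med.json.

library(sahpkit)

sweeps <- read.csv("results/run/sweeps.csv")
qc_excl <- read.csv("results/run/qc_exclusions.csv")
sweeps <- sweeps[!sweeps$cell_id %in% qc_excl$cell_id, ]

for (response in c("v_slow", "v_med")) {
  st <- cohort_inference(sweeps, response = response, m = 20,
                         seed = 20260924 + match(response, c("v_slow", "v_med")))
  lab <- if (response == "v_slow") "slow AHP" else "medium AHP"
  cat(sprintf("\n== %s ==\n", lab))
  cat(sprintf("influence screen: %d of %d observations above 4/n\n",
              length(st$influence$flagged), st$influence$n))
  cat(sprintf("interaction LRT (pooled over %d imputations): chi-square = %.2f, p = %.4f\n",
              st$m, st$lrt_interaction$chi_square, st$lrt_interaction$p_value))
  cat(sprintf("main treatment effect: chi-square = %.2f, p = %.4f\n",
              st$lrt_main$chi_square, st$lrt_main$p_value))
  if (!is.null(st$correlation) && response == "v_slow")
    cat(sprintf("sAHP vs spike count: r = %.2f (vehicle), r = %.2f (treated)\n",
                st$correlation$vehicle$r, st$correlation$treated$r))
  jsonlite::write_json(
    sahpkit:::stats_summary_json(st),
    sprintf("results/stats_%s.json", response),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
cat("\nwrote results/stats_v_slow.json, results/stats_v_med.json\n")
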