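#!/usr/bin/env Rscript
# Step 1: simulate the default two-group cohort (20 vehicle / 15 treated
# cells, 13 current steps each) and extract every per-cell and per-sweep
# feature: passive membrane properties from the -20 pA probe, spike counts
# and waveform features, and the medium/slow AHP decomposition. Applies the
# 100-450 Mohm input-resistance inclusion filter. Outputs land in
# results/run/ (truth.csv, passive.csv, sweeps.csv, first_spike.csv,
# qc_exclusions.csv, manifest.json).

library(sahpkit)

cfg <- pipeline_config(
  seed = 20260924,
  out_dir = "results/run",
  stages = c("simulate", "features", "qc"))
res <- run_pipeline(cfg)

cat(sprintf("simulated %d cells x 13 steps (%d sweeps observed)\n",
            nrow(res$features$passive), nrow(res$features$sweeps)))
cat(sprintf("QC kept %d cells; excluded: %s\n", nrow(res$qc$kept),
            if (nrow(res$qc$report)) paste(res$qc$report$cell_id, collapse = ", ")
            else "none"))
cat(sprintf("median input resistance %.1f Mohm, median sAHP decay %.2f s\n",
            median(res$features$passive$r_in),
            median(res$features$sweeps$tau_slow, na.rm = TRUE) / 1000))
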