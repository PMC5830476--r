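#!/usr/bin/env Rscript
# Step 1 — simulate the study dataset.
#
# Draws the full synthetic ADE modeling dataset from the latent
# compound-target model (300 compounds; 30 assay readouts covering 15 of 50
# targets; 50 DTAs covering all targets; 64 structure bits; 12 animal
# endpoints; 20 ADEs whose causal targets are biased toward the unassayed
# targets) plus a triplicate call table for assay QC, and writes everything
# under results/data/.

suppressPackageStartupMessages(library(wfstox))

cfg <- generator_config(seed = 1)
ds <- generate_synthetic(cfg)
write_synthetic_dataset(ds, "results/data")

trip <- generate_triplicates(cfg, call_noise = 0.02)
utils::write.csv(trip, "results/data/triplicates.csv", row.names = FALSE)

message(sprintf(
  "wrote results/data: %d compounds, %d ADEs (median %d positives), assay %.1f%% active / %.1f%% missing",
  nrow(ds$assay), ncol(ds$ades), as.integer(stats::median(colSums(ds$ades))),
  100 * mean(ds$assay == 1L, na.rm = TRUE), 100 * mean(is.na(ds$assay))
))
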