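#!/usr/bin/env Rscript
# Step 3 — fit and compare WFS model sets.
#
# Evaluates six model sets over the shared 10x 50/50 holdout plan: each
# single block (assay, structure, DTA, animal) and the combinations that
# probe whether annotations expand the biological space the assays cover
# (assay+DTA, assay+selected DTA). Writes per-split results, the summary
# table (best AUC, mean AUC, ADEs > 0.75), and the ANOVA/Bonferroni
# comparison under results/.

suppressPackageStartupMessages(library(wfstox))

cfg <- experiment_config(
  generator = generator_config(seed = 1),
  model_sets = list(
    assay = "assay",
    structure = "structure",
    animal = "animal",
    dta = "dta",
    `assay+dta` = c("assay", "dta"),
    `assay+dta_selected` = c("assay", "dta_selected")
  ),
  n_splits = 10, seed = 1,
  output_dir = "results/models"
)
out <- run_experiment(cfg)

print(out$summary_table, digits = 3)
message(sprintf(
  "ANOVA across model sets: p = %.3g; assay+DTA vs assay adjusted p = %.3g",
  out$comparison$anova_p,
  out$comparison$pairwise$p_adj[
    out$comparison$pairwise$model_a == "assay+dta" &
      out$comparison$pairwise$model_b == "assay" |
      out$comparison$pairwise$model_a == "assay" &
        out$comparison$pairwise$model_b == "assay+dta"
  ]
))
message(sprintf("%d DTAs passed the univariate screen", length(out$selected_dtas)))
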