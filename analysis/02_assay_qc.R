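#!/usr/bin/env Rscript
# Step 2 — assay reproducibility QC.
#
# Scores each simulated assay's triplicate calls with the reproducibility
# score (2 x %active match + %inactive match - %inconclusive - 2 x %mismatch)
# and grades them (A >= 90, B >= 80, C >= 70, D below). With 2% call noise
# most assays land in grades A-B, mirroring a well-behaved qHTS screen.

suppressPackageStartupMessages(library(wfstox))

trip <- triplicate_call_table(
  utils::read.csv("results/data/triplicates.csv", stringsAsFactors = FALSE)
)
report <- qc_report(trip)
utils::write.csv(report, "results/assay_qc.csv", row.names = FALSE)

message(sprintf(
  "QC on %d assays: scores %.1f-%.1f; grades: %s",
  nrow(report), min(report$score), max(report$score),
  paste(sprintf("%s=%d", names(table(report$grade)), as.integer(table(report$grade))),
    collapse = " ")
))
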