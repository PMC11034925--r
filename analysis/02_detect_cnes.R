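#!/usr/bin/env Rscript
# Stage 2 — de novo CNE detection from the two focal pairs.
#
# Each focal pair (zeb vs tet; fugu vs seab) goes through two-round
# seed-and-extend alignment, collinear chaining, reference-side netting,
# exon/repeat masking, the 100 bp / 70% sliding-window scan and the
# copy-number ("cutoffs" = 4) repeat filter. Detected elements are written
# as BED + TSV, and compared against planted truth.

suppressMessages(library(cnevol))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out_dir <- file.path("results", sprintf("run_seed%d", seed))
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- pipeline_config(seed = seed, sim = sim_config(seed = seed))
run <- run_pipeline(cfg, stages = c("simulate", "detect"))

for (nm in c("zcne", "fcne")) {
  cs <- run[[nm]]
  write.table(cs, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  qsp <- if (nm == "zcne") cfg$focal_pairs[[1]][2] else cfg$focal_pairs[[2]][2]
  ev <- eval_detection(cs, run$cohort, qsp)
  cat(sprintf("%s: %d elements | bp recall %.1f%% | bp precision %.1f%%\n",
              nm, nrow(cs), 100 * ev$bp_recall, 100 * ev$bp_precision))
}
saveRDS(run, file.path(out_dir, "run_detect.rds"))
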