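#!/usr/bin/env Rscript
# Stage 3 — cross-genome presence search and ancestral-set reconstruction.
#
# Every detected element is searched against all seven genomes (word size 6,
# two-hit seeding, E <= 1e-6, best hit per species) to build the
# presence/absence matrix. Elements supported in both basal clades form the
# ancestral repertoire; outgroup presence dates each element (vertebrate /
# Neopterygian / 3R) and per-species loss rates are tabulated.

suppressMessages(library(cnevol))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out_dir <- file.path("results", sprintf("run_seed%d", seed))
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- pipeline_config(seed = seed, sim = sim_config(seed = seed))
prev_file <- file.path(out_dir, "run_detect.rds")
prev <- if (file.exists(prev_file)) readRDS(prev_file) else NULL
run <- run_pipeline(cfg, stages = c("search", "ancestry", "zones"), prev = prev)

write_presence_matrix(run$presence, file.path(out_dir, "presence.tsv"))
write.table(run$atcnes, file.path(out_dir, "atcnes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(run$losses, file.path(out_dir, "loss_rates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(run$zones, file.path(out_dir, "zones.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

at <- run$atcnes
cat("Ancestral set:", nrow(at), "elements ( zCNE-sourced:",
    sum(at$source_set == "zCNE"), "/ fCNE-sourced:",
    sum(at$source_set == "fCNE"), ")\n")
cat("Origin categories:\n"); print(table(at$origin_category))
ev <- eval_ancestry(at, run$cohort)
cat(sprintf("Recall of recoverable planted elements: %.1f%% (n = %d)\n",
            100 * ev$recall, ev$n_eligible))
cat(sprintf("Origin dating accuracy (vs retained-outgroup truth): %.1f%%\n",
            100 * ev$category_accuracy))
cat(sprintf("  (vs birth age, incl. outgroup-lost elements: %.1f%%)\n",
            100 * ev$category_accuracy_birth))
cons <- tapply(at$conservation_score, at$origin_category, mean, na.rm = TRUE)
cat("Mean conservation score by age (expect vertebrate > neopterygian > 3R):\n")
print(round(cons[c("vertebrate", "neopterygian", "3R")], 4))
zs <- zone_class_summary(run$zones)
cat(sprintf("Zones: %d total, %d empty (%.1f%%)\n",
            zs$total, zs$empty, zs$pct_empty))
saveRDS(run, file.path(out_dir, "run_ancestry.rds"))
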