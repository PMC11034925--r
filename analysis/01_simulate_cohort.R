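#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Seven genomes descend from a common ancestor along a fixed, roughly
# clock-like tree: a distant vertebrate outgroup, a gar analog, and five
# teleost-analog species forming the two basally splitting clades
# (clade 1: zeb + tet; clade 2: til + fugu + seab). The teleost stem carries
# a whole-genome duplication. Conserved noncoding elements of three ages
# (vertebrate / Neopterygian / 3R) are planted in clusters around anchor
# genes, with per-branch losses, inversions and a slow-evolving interspersed
# repeat family. Everything downstream works from the files written here;
# ground truth goes to the truth_*.tsv tables.

suppressMessages(library(cnevol))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

out_dir <- file.path("results", sprintf("cohort_seed%d", seed))
cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg, out_dir = out_dir)
print(cohort)
print(cohort$genomes)

el <- cohort$truth$elements
cat("\nPlanted elements by age (ancestral ids):\n")
print(table(unique(el[c("ancestral_id", "age")])$age))
cat("Loss events:", nrow(cohort$truth$losses),
    "| paralog element pairs:", nrow(cohort$truth$paralog_pairs), "\n")
cat("Cohort written to", out_dir, "\n")
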