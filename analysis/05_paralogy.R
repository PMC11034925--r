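#!/usr/bin/env Rscript
# Stage 5 — CNE paralogy clustering and comparison with the vertebrate set.
#
# Nonself sequence hits within the clade-1-reference ancestral set, gated by
# target-gene paralogy, form paralogy clusters dated pre- vs post-WGD from
# the anchoring paralog relations. A vertebrate-analog reference cluster set
# (built from the planted vertebrate-age elements in the outgroup genome —
# the stand-in for an external vertebrate CNE input) is clustered with the
# same machinery and intersected by anchor orthogroups.

suppressMessages(library(cnevol))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out_dir <- file.path("results", sprintf("run_seed%d", seed))
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- pipeline_config(seed = seed, sim = sim_config(seed = seed))
prev_file <- file.path(out_dir, "run_assoc.rds")
prev <- if (file.exists(prev_file)) readRDS(prev_file) else NULL
run <- run_pipeline(cfg, stages = "paralogs", prev = prev)
co <- run$cohort

write.table(run$clusters, file.path(out_dir, "paralogy_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cl <- run$clusters
cat("Teleost-analog paralogy clusters:", nrow(cl), "\n")
if (nrow(cl)) print(table(cl$origin))

# vertebrate-analog reference clusters from the outgroup's planted elements
vsp <- co$tree$vertebrate_ids[1]
el <- co$truth$elements
vel <- el[el$species_id == vsp & el$age == "vertebrate", , drop = FALSE]
vset <- data.frame(id = paste0("v_", vel$elem_id), ref_species = vsp,
                   chrom = vel$chrom, start = vel$start, end = vel$end,
                   strand = "+", length = vel$end - vel$start,
                   mean_identity = 1, source_pair = vsp,
                   stringsAsFactors = FALSE)
vassoc <- data.frame(cne_id = vset$id,
                     target_orthogroups = paste0("OG_", vel$target_gene),
                     target_genes = vel$target_gene,
                     synteny_score = 1L, proximity_rank = 1,
                     n_candidates_ref = 1L, target_class = "ancestral",
                     stringsAsFactors = FALSE)
vhits <- self_hits(vset, co$genomes, cfg$search)
vcl <- paralogy_clusters(vhits, vassoc, co$orthology, vsp)
cat("Vertebrate-analog clusters:", nrow(vcl), "\n")
shared <- common_clusters(run$clusters, vcl)
cat("Common paralogy clusters (shared anchor orthogroups):", nrow(shared), "\n")
write.table(shared, file.path(out_dir, "common_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# member age shares within paralogous elements
at <- run$atcnes
members <- unique(unlist(strsplit(cl$members, ",")))
if (length(members)) {
  ages <- at$origin_category[match(members, at$id)]
  cat("Paralogous-element age shares (%):\n")
  print(round(100 * table(ages) / length(ages), 1))
}
saveRDS(run, file.path(out_dir, "run_paralogs.rds"))
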