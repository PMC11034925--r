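#' Evaluate detection against simulator truth
#'
#' Recall is measured over planted-element bases present in both species of
#' the focal pair (only those are detectable from that pair's alignment);
#' precision over all detected bases against every planted element of the
#' reference species.
#'
#' @param cnes detected CNE set (one focal pair).
#' @param cohort a `sim_cohort`.
#' @param query_species the other species of the focal pair.
#' @return list with `bp_recall`, `bp_precision`, `n_detected`,
#'   `n_truth_pair`.
#' @export
eval_detection <- function(cnes, cohort, query_species) {
  ref <- unique(cnes$ref_species)
  tr <- cohort$truth$elements
  t_ref <- tr[tr$species_id == ref, , drop = FALSE]
  ids_query <- tr$elem_id[tr$species_id == query_species]
  t_pair <- t_ref[t_ref$elem_id %in% ids_query, , drop = FALSE]
  det <- interval_df(cnes$chrom, cnes$start, cnes$end)
  truth_pair <- interval_df(t_pair$chrom, t_pair$start, t_pair$end)
  truth_all <- interval_df(t_ref$chrom, t_ref$start, t_ref$end)
  list(bp_recall = intervals_overlap_bp(truth_pair, det) /
         max(1L, intervals_width(truth_pair)),
       bp_precision = intervals_overlap_bp(det, truth_all) /
         max(1L, intervals_width(det)),
       n_detected = nrow(cnes), n_truth_pair = nrow(t_pair))
}

#' Match ancestral elements to planted truth
#'
#' Each inferred element is matched to the planted element of its reference
#' species that overlaps it (>= 1 bp).
#'
#' @param atcnes inferred ancestral set.
#' @param cohort a `sim_cohort`.
#' @return `atcnes` with `truth_elem`, `truth_ancestral`, `truth_age`,
#'   `truth_target` columns (`NA` when unmatched).
#' @export
match_truth <- function(atcnes, cohort) {
  tr <- cohort$truth$elements
  atcnes$truth_elem <- NA_character_
  atcnes$truth_ancestral <- NA_character_
  atcnes$truth_age <- NA_character_
  atcnes$truth_target <- NA_character_
  for (i in seq_len(nrow(atcnes))) {
    t_sp <- tr[tr$species_id == atcnes$ref_species[i] &
                 tr$chrom == atcnes$chrom[i] &
                 tr$start < atcnes$end[i] & tr$end > atcnes$start[i], ,
               drop = FALSE]
    if (nrow(t_sp)) {
      best <- which.max(pmin(t_sp$end, atcnes$end[i]) -
                          pmax(t_sp$start, atcnes$start[i]))
      atcnes$truth_elem[i] <- t_sp$elem_id[best]
      atcnes$truth_ancestral[i] <- t_sp$ancestral_id[best]
      atcnes$truth_age[i] <- t_sp$age[best]
      atcnes$truth_target[i] <- t_sp$target_gene[best]
    }
  }
  atcnes
}

#' Evaluate ancestral inference and origin dating against truth
#'
#' Eligible elements are planted copies present in at least one species of
#' each basal clade (those are recoverable in principle). Recall counts
#' eligible ancestral ids recovered in the inferred set. `category_accuracy`
#' compares origin categories with the category derivable from truth
#' outgroup retention — an element whose outgroup copies were deleted is
#' undatable from presence, so only the retained repertoire tests the
#' method; `category_accuracy_birth` scores against the planted birth age
#' regardless of retention.
#'
#' @param atcnes categorized ancestral set (after [match_truth()] or not).
#' @param cohort a `sim_cohort`.
#' @return list with `recall`, `category_accuracy`,
#'   `category_accuracy_birth`, `n_eligible`, `n_matched`.
#' @export
eval_ancestry <- function(atcnes, cohort) {
  if (is.null(atcnes$truth_elem)) atcnes <- match_truth(atcnes, cohort)
  tr <- cohort$truth$elements
  clade1 <- cohort$tree$clade1; clade2 <- cohort$tree$clade2
  in1 <- unique(tr$elem_id[tr$species_id %in% clade1])
  in2 <- unique(tr$elem_id[tr$species_id %in% clade2])
  eligible <- intersect(in1, in2)
  recovered <- unique(atcnes$truth_elem[!is.na(atcnes$truth_elem)])
  matched <- atcnes[!is.na(atcnes$truth_age), , drop = FALSE]
  # category expected from truth retention in the diagnostic outgroups
  vert_ids <- unique(tr$ancestral_id[tr$species_id %in%
                                       cohort$tree$vertebrate_ids])
  gar_ids <- unique(tr$ancestral_id[tr$species_id %in%
                                      cohort$tree$outgroup_ids])
  expected <- ifelse(matched$truth_ancestral %in% vert_ids, "vertebrate",
                     ifelse(matched$truth_ancestral %in% gar_ids,
                            "neopterygian", "3R"))
  list(recall = length(intersect(eligible, recovered)) / max(1L, length(eligible)),
       category_accuracy = mean(matched$origin_category == expected),
       category_accuracy_birth = mean(matched$origin_category == matched$truth_age),
       n_eligible = length(eligible), n_matched = nrow(matched))
}

#' Evaluate target selection against planted targets
#'
#' Correct when the selected target orthogroups contain the planted target
#' gene's orthogroup (orthogroup level, so WGD gene copies count as the
#' same target locus).
#'
#' @param associations classified associations.
#' @param atcnes matched ancestral set ([match_truth()]).
#' @param cohort a `sim_cohort`.
#' @return list with `target_accuracy` and `n_assessed`.
#' @export
eval_targets <- function(associations, atcnes, cohort) {
  if (is.null(atcnes$truth_target)) atcnes <- match_truth(atcnes, cohort)
  m <- merge(associations, atcnes[c("id", "truth_target")],
             by.x = "cne_id", by.y = "id")
  m <- m[!is.na(m$truth_target) & m$target_class %in% c("ancestral", "novel"), ,
         drop = FALSE]
  if (nrow(m) == 0) return(list(target_accuracy = NA_real_, n_assessed = 0L))
  truth_og <- paste0("OG_", sub("_b$", "", m$truth_target))
  hit <- vapply(seq_len(nrow(m)), function(i)
    truth_og[i] %in% strsplit(m$target_orthogroups[i], ",")[[1]], logical(1))
  list(target_accuracy = mean(hit), n_assessed = nrow(m))
}

#' Bootstrap z-score under a signal-destroying shuffle
#'
#' Calibration check of the bootstrap machinery: after destroying the
#' element/ancestral-target association the z-score should be
#' indistinguishable from noise (|z| < 2), unlike the planted associations.
#'
#' The default shuffle (`mode = "labels"`) permutes which orthogroups count
#' as vertebrate-CNE targets — drawing a random orthogroup set of the same
#' size from the reference species' gene complement — reclassifies the real
#' associations and recomputes the z; the mean over `n_shuffles` draws is
#' returned. This holds the genomic geometry fixed on both sides of the
#' comparison. `mode = "positions"` instead places length-matched fake
#' elements at random genomic positions; note that with clustered anchor
#' genes in cleared neighbourhoods a nearest-gene pick from a random
#' position is catchment-area-weighted toward anchors while the bootstrap
#' null draws genes uniformly, so this mode retains a small positive bias
#' at desk scale (discussed in the methods vignette).
#'
#' @param run a [run_pipeline()] result.
#' @param seed RNG seed for the shuffle.
#' @param mode `"labels"` (default) or `"positions"`.
#' @param n_shuffles label-permutation draws averaged over (labels mode).
#' @return the [bootstrap_null()] result for the shuffled set; in labels
#'   mode `z` is the mean z over the draws.
#' @export
shuffled_association_z <- function(run, seed = 1L,
                                   mode = c("labels", "positions"),
                                   n_shuffles = 5L) {
  mode <- match.arg(mode)
  co <- run$cohort
  ref <- run$config$focal_pairs[[1]][1]
  if (mode == "labels") {
    ogs_all <- unique(co$orthology$orthogroup_id[co$orthology$species_id == ref])
    k <- length(co$truth$vcne_target_orthogroups)
    zs <- numeric(n_shuffles)
    out <- NULL
    for (i in seq_len(n_shuffles)) {
      fake_set <- with_seed(derive_seed(seed, paste0("labelshuffle", i)),
                            sample(ogs_all, min(k, length(ogs_all))))
      assoc <- classify_targets(run$associations, fake_set)
      params <- run$config$assoc
      params$seed <- derive_seed(seed, paste0("labelboot", i))
      out <- bootstrap_null(assoc, co$genomes[[ref]]$genes, co$orthology,
                            fake_set, params, ref_species = ref)
      zs[i] <- out$z
    }
    out$z <- mean(zs)
    out$z_draws <- zs
    return(out)
  }
  zat <- run$atcnes[run$atcnes$ref_species == ref, , drop = FALSE]
  lens <- zat$end - zat$start
  seqlens <- genome_seqlens(co$genomes, ref)
  fake <- with_seed(seed, {
    chrom <- sample(names(seqlens), length(lens), replace = TRUE,
                    prob = seqlens / sum(seqlens))
    start <- vapply(seq_along(lens), function(i)
      sample.int(seqlens[[chrom[i]]] - lens[i], 1L) - 1L, integer(1))
    data.frame(id = sprintf("shuf_%04d", seq_along(lens)),
               ref_species = ref, chrom = chrom, start = start,
               end = start + lens, strand = "+", stringsAsFactors = FALSE)
  })
  pm <- data.frame(query_id = fake$id, species_id = ref, chrom = fake$chrom,
                   start = fake$start, end = fake$end, strand = "+",
                   score = NA_real_, bitscore = NA_real_, evalue = 0,
                   identity = 1, q_cov_start = 0L, q_cov_end = lens,
                   stringsAsFactors = FALSE)
  params <- run$config$assoc
  params$min_synteny_species <- 1L
  params$seed <- derive_seed(seed, "shuffle-bootstrap")
  genes_by_species <- lapply(co$genomes, function(g) g$genes)
  assoc <- associate_cnes(fake, pm, genes_by_species, co$orthology, params)
  assoc <- classify_targets(assoc, co$truth$vcne_target_orthogroups)
  bootstrap_null(assoc, co$genomes[[ref]]$genes, co$orthology,
                 co$truth$vcne_target_orthogroups, params, ref_species = ref)
}

#' Full truth-based evaluation of a pipeline run
#'
#' @param run a [run_pipeline()] result.
#' @return list of evaluation summaries (detection per focal pair, ancestry,
#'   targets, bootstrap, phylogeny RF distance).
#' @export
evaluate_run <- function(run) {
  co <- run$cohort
  fp1 <- run$config$focal_pairs[[1]]; fp2 <- run$config$focal_pairs[[2]]
  at <- match_truth(run$atcnes, co)
  rf <- if (!is.null(run$tree_nj)) {
    true_tele <- ape::keep.tip(co$tree$phylo, intersect(
      co$tree$phylo$tip.label, run$tree_nj$tip.label))
    rf_distance(run$tree_nj, true_tele)
  } else NA_integer_
  list(detection_z = eval_detection(run$zcne, co, fp1[2]),
       detection_f = eval_detection(run$fcne, co, fp2[2]),
       ancestry = eval_ancestry(at, co),
       targets = eval_targets(run$associations, at, co),
       bootstrap = run$bootstrap,
       rf = rf)
}
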