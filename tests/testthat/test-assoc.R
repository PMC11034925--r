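toy_genes <- function(sp, starts, ids) {
  data.frame(chrom = "c1", start = starts, end = starts + 1000L, strand = "+",
             gene_id = ids, stringsAsFactors = FALSE)
}

toy_orthology <- function(species, genes, ogs,
                          partners = "", origins = "none") {
  data.frame(species_id = rep(species, each = length(genes)),
             gene_id = rep(genes, length(species)),
             orthogroup_id = rep(ogs, length(species)),
             paralog_partner_ids = rep(partners, length.out =
                                         length(genes) * length(species)),
             paralog_origin = rep(origins, length.out =
                                    length(genes) * length(species)),
             stringsAsFactors = FALSE)
}

test_that("the 1 Mb window rule and distance-0 containment hold", {
  pm <- data.frame(query_id = "c", species_id = "s1", chrom = "c1",
                   start = 2000000L, end = 2000200L, strand = "+",
                   score = NA_real_, bitscore = NA_real_, evalue = 0,
                   identity = 1, q_cov_start = 0L, q_cov_end = 200L,
                   stringsAsFactors = FALSE)
  genes <- toy_genes("s1", c(1500000L, 800000L, 3200001L, 1999500L),
                     c("near", "far", "beyond", "host"))
  cand <- candidate_genes("c", pm, list(s1 = genes), window = 1000000L)
  expect_setequal(cand$gene_id, c("near", "host"))  # 1.2 Mb away excluded
  expect_equal(cand$distance[cand$gene_id == "host"], 0L)  # overlapping
  expect_equal(cand$distance[cand$gene_id == "near"], 2000000L - 1501000L)
  # oracle: brute-force interval check over all genes
  brute <- genes$gene_id[pmax(genes$start - 2000200L, 2000000L - genes$end,
                              0L) <= 1000000L &
                           genes$end > 2000000L - 1000000L &
                           genes$start < 2000200L + 1000000L]
  expect_setequal(cand$gene_id, brute)
})

test_that("synteny scores count species and ranks average with ties", {
  # one orthogroup nearest in 3 species, second-nearest in 2
  cand <- rbind(
    data.frame(species_id = c("s1", "s2", "s3"), gene_id = "gA",
               distance = 100L, rank = 1, stringsAsFactors = FALSE),
    data.frame(species_id = c("s4", "s5"), gene_id = "gA", distance = 500L,
               rank = 2, stringsAsFactors = FALSE),
    data.frame(species_id = c("s4", "s5"), gene_id = "gB", distance = 100L,
               rank = 1, stringsAsFactors = FALSE))
  ortho <- toy_orthology(paste0("s", 1:5), c("gA", "gB"), c("OGA", "OGB"))
  sc <- synteny_scores(cand, ortho)
  a <- sc[sc$orthogroup == "OGA", ]
  expect_equal(a$score, 5L)
  expect_equal(a$proximity_rank, (1 + 1 + 1 + 2 + 2) / 5)
  expect_equal(sc[sc$orthogroup == "OGB", "score"], 2L)
})

test_that("candidate ranks use fractional ties and feed selection correctly", {
  pm <- data.frame(query_id = "c", species_id = "s1", chrom = "c1",
                   start = 10000L, end = 10100L, strand = "+",
                   score = NA_real_, bitscore = NA_real_, evalue = 0,
                   identity = 1, q_cov_start = 0L, q_cov_end = 100L,
                   stringsAsFactors = FALSE)
  genes <- toy_genes("s1", c(12000L, 7100L, 20000L), c("g1", "g2", "g3"))
  cand <- candidate_genes("c", pm, list(s1 = genes), window = 1000000L)
  # g1 and g2 both 1900 bp away -> tied fractional rank 1.5
  expect_equal(sort(cand$rank[cand$gene_id %in% c("g1", "g2")]), c(1.5, 1.5))
  expect_equal(cand$rank[cand$gene_id == "g3"], 3)
})

test_that("target selection enforces the species cutoff and keeps exact ties", {
  scored <- data.frame(orthogroup = c("A", "B", "C"), score = c(4L, 6L, 6L),
                       proximity_rank = c(1.0, 1.5, 1.5),
                       genes = c("a", "b", "c"), stringsAsFactors = FALSE)
  sel <- select_targets(scored, assoc_params(min_synteny_species = 5L))
  expect_setequal(sel$orthogroup, c("B", "C"))  # tie retention
  none <- select_targets(scored[1, ], assoc_params(min_synteny_species = 5L))
  expect_equal(nrow(none), 0L)
  # oracle: brute-force argmax/argmin over the table
  brute <- scored[scored$score >= 5, ]
  brute <- brute[brute$score == max(brute$score), ]
  brute <- brute[brute$proximity_rank == min(brute$proximity_rank), ]
  expect_setequal(sel$orthogroup, brute$orthogroup)
})

test_that("classification splits ancestral and novel targets", {
  assoc <- data.frame(cne_id = c("c1", "c2", "c3"),
                      target_orthogroups = c("OG1", "OG9", ""),
                      target_genes = c("g1", "g9", ""),
                      synteny_score = c(6L, 6L, NA), proximity_rank = 1,
                      n_candidates_ref = 3L, target_class = "unclassified",
                      stringsAsFactors = FALSE)
  out <- classify_targets(assoc, c("OG1", "OG2"))
  expect_equal(out$target_class, c("ancestral", "novel", "none"))
})

test_that("bootstrap matches exhaustive enumeration on a tiny case", {
  # 3 CNEs, 4 genes, 2 in ancestral orthogroups, draw sizes 1, 1, 2
  genes <- toy_genes("s1", c(0L, 5000L, 10000L, 15000L), paste0("g", 1:4))
  ortho <- toy_orthology("s1", paste0("g", 1:4), paste0("OG", 1:4))
  assoc <- data.frame(cne_id = c("c1", "c2", "c3"),
                      target_orthogroups = c("OG1", "OG3", "OG2,OG4"),
                      target_genes = c("g1", "g3", "g2,g4"),
                      synteny_score = 6L, proximity_rank = 1,
                      n_candidates_ref = 4L,
                      target_class = c("ancestral", "novel", "ancestral"),
                      stringsAsFactors = FALSE)
  vcne <- c("OG1", "OG2")
  params <- assoc_params(n_bootstrap = 40000L, seed = 99L)
  bn <- bootstrap_null(assoc, genes, ortho, vcne, params, ref_species = "s1")
  # exhaustive enumeration of all draws: P(hit | k=1) = 2/4,
  # P(hit | k=2) = 1 - C(2,2)/C(4,2) = 5/6
  p <- c(0.5, 0.5, 5 / 6)
  expect_equal(bn$observed, 2L)
  expect_equal(bn$mean, sum(p), tolerance = 0.02)
  expect_equal(bn$sd, sqrt(sum(p * (1 - p))), tolerance = 0.02)
  # determinism
  bn2 <- bootstrap_null(assoc, genes, ortho, vcne, params, ref_species = "s1")
  expect_identical(bn[c("mean", "sd", "z")], bn2[c("mean", "sd", "z")])
})

test_that("an observation at the null mean gives z near 0; zero sd flags Inf", {
  genes <- toy_genes("s1", c(0L, 5000L), c("g1", "g2"))
  ortho <- toy_orthology("s1", c("g1", "g2"), c("OG1", "OG2"))
  assoc <- data.frame(cne_id = "c1", target_orthogroups = "OG1",
                      target_genes = "g1", synteny_score = 6L,
                      proximity_rank = 1, n_candidates_ref = 2L,
                      target_class = "novel", stringsAsFactors = FALSE)
  # all genes ancestral -> every draw hits: sd = 0, observed 0 below mean 1
  bn <- bootstrap_null(assoc, genes, ortho, c("OG1", "OG2"),
                       assoc_params(n_bootstrap = 200L, seed = 1L), "s1")
  expect_true(bn$degenerate)
  expect_identical(bn$z, -Inf)
})

test_that("planted targets are recovered and the bootstrap separates signal", {
  run <- small_run()
  ev <- eval_targets(run$associations, match_truth(run$atcnes, run$cohort),
                     run$cohort)
  expect_gte(ev$target_accuracy, 0.9)
  expect_gt(run$bootstrap$z, 5)
  shuf <- shuffled_association_z(run, seed = 11)
  expect_lt(abs(shuf$z), 2)
})
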