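test_that("zero branch length leaves sequences unchanged; same seed repeats", {
  s <- random_dna(2000L)
  expect_identical(evolve_sequence(s, 0, seed = 3), s)
  expect_identical(evolve_sequence(s, 0.3, seed = 3),
                   evolve_sequence(s, 0.3, seed = 3))
  expect_false(identical(evolve_sequence(s, 0.3, seed = 3),
                         evolve_sequence(s, 0.3, seed = 4)))
})

test_that("observed substitution fraction matches the Jukes-Cantor closed form", {
  set.seed(20)
  n <- 100000L
  s <- random_dna(n)
  s2 <- evolve_sequence(s, 0.2, seed = 21)
  p <- 0.75 * (1 - exp(-0.2 * 4 / 3))  # ~0.1770
  obs <- mean(strsplit(s, "")[[1]] != strsplit(s2, "")[[1]])
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("non-ACGT sites never mutate and region scalings apply", {
  s <- paste0(strrep("N", 500), random_dna(500L))
  out <- evolve_sequence(s, 5, seed = 1)
  expect_identical(substr(out, 1, 500), strrep("N", 500))
  regions <- data.frame(start = 0L, end = 500L, scale = 1e-6)
  s2 <- random_dna(1000L)
  out2 <- evolve_sequence(s2, 1, rate_scale_by_region = regions, seed = 2)
  expect_identical(substr(out2, 1, 500), substr(s2, 1, 500))
  expect_false(identical(substr(out2, 501, 1000), substr(s2, 501, 1000)))
})

test_that("with no losses every planted element reaches every eligible species", {
  co <- noloss_cohort()
  cfg <- co$config
  el <- co$truth$elements
  teleosts <- c(co$tree$clade1, co$tree$clade2)
  n_planted <- cfg$n_cne_vertebrate + cfg$n_cne_neopterygian + cfg$n_cne_3r
  for (sp in names(co$genomes)) {
    e <- el[el$species_id == sp, ]
    if (sp %in% co$tree$vertebrate_ids) {
      expect_equal(nrow(e), cfg$n_cne_vertebrate)
      expect_setequal(unique(e$age), "vertebrate")
    } else if (sp %in% co$tree$outgroup_ids) {
      expect_equal(nrow(e), cfg$n_cne_vertebrate + cfg$n_cne_neopterygian)
    } else {
      expect_true(sp %in% teleosts)
      # WGD doubling: two copies of every pre-WGD element (except the pre-WGD
      # pair elements, whose anchors always revert to single copy), one of
      # each 3R element
      n_dup <- cfg$n_cne_vertebrate + cfg$n_cne_neopterygian -
        2L * cfg$n_pre_wgd_pairs
      expect_equal(nrow(e), cfg$n_cne_vertebrate + cfg$n_cne_neopterygian +
                     n_dup + cfg$n_cne_3r)
      expect_equal(sum(grepl("_b$", e$elem_id)), n_dup)
    }
  }
  # conservation bookkeeping: all ancestral ids distinct and accounted for
  expect_equal(length(unique(el$ancestral_id)), n_planted)
})

test_that("per-species element counts equal planted minus root-path losses", {
  co <- small_cohort()
  cfg <- co$config
  phy <- co$tree$phylo
  el <- co$truth$elements
  losses <- co$truth$losses
  ages_for <- function(path) {
    a <- "vertebrate"
    if ("neo" %in% path || any(c("gar", "tel", "c1", "c2") %in% path))
      a <- c(a, "neopterygian")
    if ("tel" %in% path) a <- c(a, "3R")
    a
  }
  planted <- unique(el[!grepl("_b$", el$elem_id), c("elem_id", "age")])
  # replay loss bookkeeping over each tip's root path for copy-a elements
  for (sp in c("zeb", "gar", "seab", "vert_out")) {
    tip <- which(phy$tip.label == sp)
    path <- character(0)
    node <- tip
    repeat {
      edge <- which(phy$edge[, 2] == node)
      if (!length(edge)) break
      lab <- if (node <= length(phy$tip.label)) phy$tip.label[node]
      else phy$node.label[node - length(phy$tip.label)]
      path <- c(path, lab)
      node <- phy$edge[edge, 1]
    }
    lost_here <- losses$elem_id[losses$branch %in% path]
    expected <- setdiff(planted$elem_id[planted$age %in% ages_for(path)],
                        lost_here)
    present <- el$elem_id[el$species_id == sp & !grepl("_b$", el$elem_id)]
    expect_setequal(present, expected)
  }
})

test_that("identical configs reproduce byte-identical cohort files", {
  cfg <- small_sim_config(seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
})

test_that("planted elements evolve slower than their neutral flanks", {
  cfg <- small_sim_config(seed = 9, inversion_rate = 0,
                          loss_prob_per_branch = 0)
  co <- simulate_cohort(cfg)
  el <- co$truth$elements
  ez <- el[el$species_id == "zeb" & !grepl("_b$", el$elem_id), ]
  et <- el[el$species_id == "tet", ]
  ident <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  el_id <- flank_id <- numeric(0)
  for (i in seq_len(nrow(ez))) {
    j <- match(ez$elem_id[i], et$elem_id)
    if (is.na(j)) next
    a <- genome_subseq(co$genomes, "zeb", ez$chrom[i], ez$start[i], ez$end[i])
    b <- genome_subseq(co$genomes, "tet", et$chrom[j], et$start[j], et$end[j])
    el_id <- c(el_id, ident(a, b))
    # 100 bp immediately left of the element (same offset in both species)
    fa <- genome_subseq(co$genomes, "zeb", ez$chrom[i], ez$start[i] - 100L, ez$start[i])
    fb <- genome_subseq(co$genomes, "tet", et$chrom[j], et$start[j] - 100L, et$start[j])
    flank_id <- c(flank_id, ident(fa, fb))
  }
  expect_gt(length(el_id), 10)
  expect_gt(mean(el_id), mean(flank_id) + 0.2)
})

test_that("a cohort without genes is valid and carries no target truth", {
  cfg <- small_sim_config(seed = 5, n_genes = 0L, n_anchor_ancestral = 0L,
                          n_anchor_novel = 0L, n_pre_wgd_pairs = 0L,
                          n_cne_vertebrate = 6L, n_cne_neopterygian = 4L,
                          n_cne_3r = 4L)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$genomes$zeb$genes), 0L)
  expect_equal(nrow(co$genomes$zeb$exons), 0L)
  expect_true(all(is.na(co$truth$elements$target_gene)))
  expect_gt(nrow(co$truth$elements), 0L)
})

test_that("the indel mode changes genome lengths but keeps features intact", {
  cfg <- small_sim_config(seed = 6, indel_rate = 2e-6, inversion_rate = 0)
  co <- simulate_cohort(cfg)
  base <- small_cohort()
  expect_false(identical(unname(genome_seqlens(co$genomes, "zeb")),
                         unname(genome_seqlens(base$genomes, "zeb"))))
  el <- co$truth$elements
  for (sp in unique(el$species_id)) {
    lens <- genome_seqlens(co$genomes, sp)
    e <- el[el$species_id == sp, ]
    expect_true(all(e$end <= lens[e$chrom]))
  }
})

test_that("a divergence event erases an element's extra conservation", {
  base_cfg <- small_sim_config(seed = 8, inversion_rate = 0,
                               loss_prob_per_branch = 0)
  co0 <- simulate_cohort(base_cfg)
  target <- co0$truth$elements$elem_id[co0$truth$elements$age == "vertebrate"][1]
  div_cfg <- small_sim_config(seed = 8, inversion_rate = 0,
                              loss_prob_per_branch = 0,
                              divergence_events = data.frame(
                                elem_id = target, branch = "zeb",
                                stringsAsFactors = FALSE))
  co1 <- simulate_cohort(div_cfg)
  ident_pair <- function(co) {
    ez <- co$truth$elements[co$truth$elements$species_id == "zeb" &
                              co$truth$elements$elem_id == target, ]
    et <- co$truth$elements[co$truth$elements$species_id == "tet" &
                              co$truth$elements$elem_id == target, ]
    a <- genome_subseq(co$genomes, "zeb", ez$chrom, ez$start, ez$end)
    b <- genome_subseq(co$genomes, "tet", et$chrom, et$start, et$end)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  expect_gt(ident_pair(co0), ident_pair(co1) + 0.1)
})
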