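# helper to build a toy presence matrix row
pm_row <- function(id, sp, chrom = "c1", start = 0L, end = 100L, strand = "+") {
  data.frame(query_id = id, species_id = sp, chrom = chrom, start = start,
             end = end, strand = strand, score = NA_real_, bitscore = NA_real_,
             evalue = 1e-10, identity = 0.9, q_cov_start = 0L,
             q_cov_end = end - start, stringsAsFactors = FALSE)
}

toy_cnes <- function(ids, ref, starts) {
  data.frame(id = ids, ref_species = ref, chrom = "c1", start = starts,
             end = starts + 100L, strand = "+", length = 100L,
             mean_identity = 0.9, source_pair = ref, stringsAsFactors = FALSE)
}

toy_params <- ancestry_params(clade1 = c("A1", "A2"), clade2 = c("B1", "B2"),
                              neopterygian_outgroup = "gar",
                              vertebrate_outgroup = "vert")

test_that("ancestral inference matches manual enumeration of a toy matrix", {
  # 5 clade-1 elements (z1..z5), 4 clade-2 elements (f1..f4); f2 overlaps z1
  # in the clade-1 reference species
  z <- toy_cnes(paste0("z", 1:5), "A1", seq(0L, 4000L, by = 1000L))
  f <- toy_cnes(paste0("f", 1:4), "B1", seq(0L, 3000L, by = 1000L))
  pm <- rbind(
    pm_row("z1", "B1", start = 500L, end = 600L),  # cross-clade: keep
    pm_row("z2", "B2"),                            # cross-clade: keep
    pm_row("z3", "A2"),                            # clade-1 only: excluded
    # z4: no hits beyond reference -> excluded; z5 in clade 2: keep
    pm_row("z5", "B1", start = 5000L, end = 5100L),
    pm_row("f1", "A1", start = 7000L, end = 7100L),  # keep
    pm_row("f2", "A1", start = 20L, end = 120L),     # overlaps z1 -> excluded
    pm_row("f3", "B2"),                              # clade-2 only: excluded
    pm_row("f4", "A2"))                              # keep (fallback species)
  # reference self-rows
  pm <- rbind(pm,
              do.call(rbind, lapply(1:5, function(i)
                pm_row(paste0("z", i), "A1", start = (i - 1L) * 1000L,
                       end = (i - 1L) * 1000L + 100L))),
              do.call(rbind, lapply(1:4, function(i)
                pm_row(paste0("f", i), "B1", start = (i - 1L) * 1000L,
                       end = (i - 1L) * 1000L + 100L))))
  at <- infer_ancestral_set(z, f, pm, toy_params)
  expect_setequal(at$id, c("z1", "z2", "z5", "f1", "f4"))
  expect_equal(sum(at$source_set == "zCNE"), 3L)
})

test_that("origin categorisation follows the outgroup precedence rules", {
  at <- toy_cnes(c("e1", "e2", "e3"), "A1", c(0L, 1000L, 2000L))
  pm <- rbind(pm_row("e1", "vert"), pm_row("e1", "gar"),  # vertebrate wins
              pm_row("e2", "gar"),                         # gar only
              pm_row("e3", "B1"))                          # teleosts only
  out <- categorize_origin(at, pm, toy_params)
  expect_equal(out$origin_category, c("vertebrate", "neopterygian", "3R"))
})

test_that("loss rates reproduce hand arithmetic and are additive", {
  # 10 elements: 4 vertebrate, 3 neopterygian, 3 3R
  at <- toy_cnes(sprintf("e%02d", 1:10), "A1", seq(0L, 9000L, by = 1000L))
  at$origin_category <- rep(c("vertebrate", "neopterygian", "3R"), c(4, 3, 3))
  # species S misses 1 vertebrate (e01) and 2 3R (e08, e09)
  present <- setdiff(at$id, c("e01", "e08", "e09"))
  pm <- do.call(rbind, lapply(present, function(id) pm_row(id, "S")))
  pm <- rbind(pm, do.call(rbind, lapply(at$id, function(id) pm_row(id, "Full"))))
  lr <- loss_rates(at, pm, species = c("S", "Full"))
  s <- lr[lr$species_id == "S", ]
  expect_equal(s$pct_vertebrate, 10)
  expect_equal(s$pct_neopterygian, 0)
  expect_equal(s$pct_3r, 20)
  expect_equal(s$pct_total, 30)
  expect_equal(s$pct_vertebrate + s$pct_neopterygian + s$pct_3r, s$pct_total)
  expect_equal(lr[lr$species_id == "Full", "pct_total"], 0)
})

test_that("zone tiling counts partial windows and classifies novelty", {
  gs <- genome_set(list(ref = list(sequences = c(
    chrA = random_dna(1200000L) ))))
  at <- toy_cnes(c("v1", "n1", "r1"), "ref", c(10000L, 510000L, 1150000L))
  at$chrom <- "chrA"
  at$origin_category <- c("vertebrate", "neopterygian", "3R")
  p <- ancestry_params(clade1 = "x", clade2 = "y",
                       neopterygian_outgroup = "g", vertebrate_outgroup = "v")
  zones <- zone_profile(at, gs, "ref", p)
  # 1.2 Mb -> 3 zones (500 kb, 500 kb, 200 kb)
  expect_equal(nrow(zones), 3L)
  expect_equal(zones$end - zones$start, c(500000L, 500000L, 200000L))
  expect_equal(zones$class,
               c("vertebrate-containing", "novel-neopterygian", "novel-3R"))
  expect_equal(attr(zones, "n_mapped"), 3L)
  # corrupt input is a hard error
  bad <- at; bad$start[1] <- 2000000L; bad$end[1] <- 2000100L
  expect_error(zone_profile(bad, gs, "ref", p), "beyond chromosome")
})

test_that("zone counts match an independent binning loop on a toy genome", {
  set.seed(40)
  gs <- genome_set(list(ref = list(sequences = c(chrA = random_dna(900000L),
                                                 chrB = random_dna(700000L)))))
  n <- 12L
  at <- toy_cnes(sprintf("e%02d", 1:n), "ref",
                 starts = sample.int(650000L, n))
  at$chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  at$origin_category <- sample(c("vertebrate", "neopterygian", "3R"), n, TRUE)
  p <- ancestry_params(clade1 = "x", clade2 = "y",
                       neopterygian_outgroup = "g", vertebrate_outgroup = "v")
  zones <- zone_profile(at, gs, "ref", p)
  # oracle: direct interval assignment
  for (i in seq_len(nrow(zones))) {
    z <- zones[i, ]
    inz <- at$chrom == z$chrom & at$start >= z$start & at$start < z$end
    expect_equal(z$n_vertebrate, sum(at$origin_category[inz] == "vertebrate"))
    expect_equal(z$n_3r, sum(at$origin_category[inz] == "3R"))
  }
  expect_equal(sum(zones$n_vertebrate + zones$n_neopterygian + zones$n_3r), n)
})

test_that("conservation scores follow the planted age ordering on the cohort", {
  run <- small_run()
  at <- run$atcnes
  by_cat <- tapply(at$conservation_score, at$origin_category, mean, na.rm = TRUE)
  expect_gt(by_cat[["vertebrate"]], by_cat[["neopterygian"]])
  expect_gt(by_cat[["neopterygian"]], by_cat[["3R"]])
  # identical sequences give score 1; two species at known identity average it
  expect_true(all(at$conservation_score <= 1, na.rm = TRUE))
})

test_that("the category partition is exhaustive on the cohort", {
  run <- small_run()
  at <- run$atcnes
  counts <- table(factor(at$origin_category,
                         c("vertebrate", "neopterygian", "3R")))
  part <- category_partition(setNames(as.numeric(counts), names(counts)))
  expect_equal(part$total, nrow(at))
})
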