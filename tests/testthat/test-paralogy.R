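toy_set <- function(gs, coords) {
  data.frame(id = names(coords), ref_species = "sp", chrom = "c1",
             start = vapply(coords, `[`, 0L, 1),
             end = vapply(coords, `[`, 0L, 2), strand = "+",
             length = vapply(coords, function(x) x[2] - x[1], 0L),
             mean_identity = 0.9, source_pair = "sp", stringsAsFactors = FALSE)
}

test_that("unique sequences give no self hits; planted families give pairs", {
  set.seed(50)
  host <- random_dna(30000L)
  seg <- random_dna(250L)
  host <- plant(host, seg, 2000L)
  host <- plant(host, seg, 10000L, mut = 0.15)       # pair at ~85% identity
  trip <- random_dna(200L)
  for (p in c(15000L, 20000L, 25000L)) host <- plant(host, trip, p, mut = 0.05)
  gs <- genome_set(list(sp = list(sequences = c(c1 = host))))
  cnes <- toy_set(gs, list(u1 = c(5000L, 5250L), u2 = c(7000L, 7200L)))
  expect_equal(nrow(self_hits(cnes, gs)), 0L)
  fam <- toy_set(gs, list(a = c(2000L, 2250L), b = c(10000L, 10250L),
                          t1 = c(15000L, 15200L), t2 = c(20000L, 20200L),
                          t3 = c(25000L, 25200L)))
  hits <- self_hits(fam, gs)
  expect_true(any(hits$a == "a" & hits$b == "b"))
  # triplet family: 3 pairs forming one connected component
  tp <- hits[hits$a %in% c("t1", "t2", "t3") & hits$b %in% c("t1", "t2", "t3"), ]
  expect_equal(nrow(tp), 3L)
  g <- igraph::graph_from_data_frame(tp[c("a", "b")], directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
})

mk_assoc <- function(ids, genes, ogs) {
  data.frame(cne_id = ids, target_orthogroups = ogs, target_genes = genes,
             synteny_score = 6L, proximity_rank = 1, n_candidates_ref = 3L,
             target_class = "ancestral", stringsAsFactors = FALSE)
}

test_that("sequence-similar pairs without paralogous targets never cluster", {
  pairs <- data.frame(a = "x1", b = "x2", score = 100, evalue = 1e-20,
                      identity = 0.9, stringsAsFactors = FALSE)
  assoc <- mk_assoc(c("x1", "x2"), c("g1", "g2"), c("OG1", "OG2"))
  ortho <- data.frame(species_id = "sp", gene_id = c("g1", "g2"),
                      orthogroup_id = c("OG1", "OG2"),
                      paralog_partner_ids = "", paralog_origin = "none",
                      stringsAsFactors = FALSE)
  cl <- paralogy_clusters(pairs, assoc, ortho, "sp")
  expect_equal(nrow(cl), 0L)
})

test_that("an OTX-style locus reproduces the planted cluster structure", {
  # two pre-WGD elements anchored on an ancient gene pair, plus two pairs of
  # post-WGD duplicated elements anchored on WGD gene copies
  pairs <- data.frame(
    a = c("preA", "dupA", "dupC"),
    b = c("preB", "dupB", "dupD"),
    score = 100, evalue = 1e-20, identity = 0.9, stringsAsFactors = FALSE)
  assoc <- mk_assoc(c("preA", "preB", "dupA", "dupB", "dupC", "dupD"),
                    c("gA", "gB", "gX", "gX_b", "gX", "gX_b"),
                    c("OGA", "OGB", "OGX", "OGX", "OGX", "OGX"))
  ortho <- data.frame(
    species_id = "sp", gene_id = c("gA", "gB", "gX", "gX_b"),
    orthogroup_id = c("OGA", "OGB", "OGX", "OGX"),
    paralog_partner_ids = c("gB", "gA", "gX_b", "gX"),
    paralog_origin = c("pre-WGD", "pre-WGD", "post-WGD", "post-WGD"),
    stringsAsFactors = FALSE)
  cl <- paralogy_clusters(pairs, assoc, ortho, "sp")
  expect_equal(nrow(cl), 3L)
  expect_equal(sort(cl$origin), c("post-WGD", "post-WGD", "pre-WGD"))
  pre <- cl[cl$origin == "pre-WGD", ]
  expect_equal(pre$members, "preA,preB")
  expect_setequal(strsplit(pre$anchor_orthogroups, ",")[[1]], c("OGA", "OGB"))
})

test_that("cluster membership equals a union-find closure of kept edges", {
  set.seed(51)
  for (case in 1:10) {
    n <- sample(4:9, 1)
    ids <- paste0("e", seq_len(n))
    m <- sample(2:6, 1)
    pairs <- unique(data.frame(a = sample(ids, m, TRUE),
                               b = sample(ids, m, TRUE),
                               stringsAsFactors = FALSE))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    if (!nrow(pairs)) next
    pairs$score <- 100; pairs$evalue <- 1e-20; pairs$identity <- 0.9
    assoc <- mk_assoc(ids, "gX", "OGX")  # all same target: every edge kept
    ortho <- data.frame(species_id = "sp", gene_id = "gX",
                        orthogroup_id = "OGX", paralog_partner_ids = "",
                        paralog_origin = "none", stringsAsFactors = FALSE)
    cl <- paralogy_clusters(pairs, assoc, ortho, "sp")
    # union-find oracle
    parent <- setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (i in seq_len(nrow(pairs)))
      parent[[find(pairs$a[i])]] <- find(pairs$b[i])
    groups <- split(ids, vapply(ids, find, ""))
    groups <- Filter(function(g) length(g) >= 2, groups)
    touched <- unique(c(pairs$a, pairs$b))
    expect_setequal(unname(cl$members),
                    unname(vapply(groups, function(g)
                      paste(sort(intersect(g, touched)), collapse = ","), "")))
  }
})

test_that("common clusters are matched by anchor orthogroup intersection", {
  ca <- data.frame(cluster_id = c("a1", "a2", "a3"),
                   members = "x", n_members = 2L,
                   anchor_orthogroups = c("OG1,OG2", "OG3", "OG9"),
                   origin = "pre-WGD", stringsAsFactors = FALSE)
  cb <- data.frame(cluster_id = c("b1", "b2", "b3", "b4"),
                   members = "y", n_members = 2L,
                   anchor_orthogroups = c("OG2", "OG3,OG4", "OG7", "OG8"),
                   origin = "pre-WGD", stringsAsFactors = FALSE)
  cc <- common_clusters(ca, cb)
  expect_equal(nrow(cc), 2L)  # set-intersection enumeration: 2 shared anchors
  expect_setequal(paste(cc$cluster_a, cc$cluster_b), c("a1 b1", "a2 b2"))
  expect_equal(nrow(common_clusters(ca[3, ], cb[3:4, ])), 0L)
})

test_that("WGD-retained element pairs land in post-WGD clusters on the cohort", {
  cfg <- small_sim_config(seed = 13, wgd_retention = 1, wgd_retention_genes = 1,
                          loss_prob_per_branch = 0)
  run <- run_pipeline(pipeline_config(seed = 13, sim = cfg),
                      stages = c("simulate", "detect", "search", "ancestry",
                                 "associate", "paralogs"))
  cl <- run$clusters
  truth_pairs <- run$cohort$truth$paralog_pairs
  post <- truth_pairs[truth_pairs$origin == "3R", ]
  # at least half of the fully-retained duplicate pairs must be recovered in
  # post-WGD clusters (members are matched through truth coordinates)
  at <- match_truth(run$atcnes, run$cohort)
  hit <- 0L
  for (i in seq_len(nrow(post))) {
    ca <- at$id[!is.na(at$truth_elem) & at$truth_elem == post$a[i]]
    cb <- at$id[!is.na(at$truth_elem) & at$truth_elem == post$b[i]]
    if (!length(ca) || !length(cb)) next
    inpost <- cl[cl$origin == "post-WGD", ]
    together <- any(vapply(strsplit(inpost$members, ","), function(m)
      any(ca %in% m) && any(cb %in% m), logical(1)))
    if (together) hit <- hit + 1L
  }
  expect_gte(hit, ceiling(nrow(post) / 2))
})
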