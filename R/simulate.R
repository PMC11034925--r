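#' Configuration for the genome-evolution simulator
#'
#' The simulator evolves a root genome along a fixed species tree and plants
#' conserved noncoding elements (CNEs) of three evolutionary ages:
#' vertebrate-age elements exist at the root, Neopterygian-age elements are
#' gained on the branch leading to the gar + teleost ancestor, and 3R-age
#' elements are gained on the teleost stem immediately after a whole-genome
#' duplication (WGD) on that same branch. Elements, exons, repeats and a
#' planted TAATTA-style motif evolve under Jukes-Cantor substitution with
#' region-specific rate scalings; losses are whole-element deletions;
#' inversions rearrange feature-free breakpoints. Defaults describe a
#' seven-species cohort (two-species clade 1, three-species clade 2, a gar
#' analog and a distant vertebrate outgroup) with roughly clock-like neutral
#' depths of ~0.7 substitutions/site and a focal-pair divergence of ~0.8,
#' deep enough that neutral sequence (~50% identity) falls below both the
#' aligner's score threshold and the 70%/100 bp detection rule while planted
#' elements (>=85% identity) stay well above them.
#'
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @param tree_newick species tree with branch lengths in expected
#'   substitutions/site and labelled internal nodes.
#' @param clade1,clade2 the two basally splitting teleost clades.
#' @param outgroup_ids gar-analog species.
#' @param vertebrate_ids vertebrate outgroup species.
#' @param wgd_branch internal-node label whose incoming branch carries the WGD.
#' @param birth_nodes named list mapping age class to the node at (and below)
#'   which elements of that age are constrained.
#' @param n_chrom,chrom_length chromosome count and length (bp) of the root.
#' @param n_genes total genes, including anchors.
#' @param exons_per_gene,exon_length,intron_length gene structure (bp).
#' @param n_anchor_ancestral,n_anchor_novel,n_pre_wgd_pairs anchor gene
#'   counts: ancestral anchors host vertebrate-age elements (and most younger
#'   ones), novel anchors host only gained elements, pre-WGD pairs are
#'   ancient gene duplicates hosting duplicated vertebrate-age element pairs.
#' @param anchor_clearance minimum distance (bp) from an anchor gene to any
#'   other gene, so that the anchor is always its elements' nearest gene.
#' @param element_offset_range per-element gap range (bp) between successive
#'   features of an anchor's element cluster; clusters stay well inside
#'   `anchor_clearance`.
#' @param n_cne_vertebrate,n_cne_neopterygian,n_cne_3r planted element counts
#'   (vertebrate count includes the pre-WGD pair elements).
#' @param cne_length_range element length range (bp).
#' @param cne_rate_scale named substitution rate scalings per age class, in
#'   (0, 1]; older classes are more constrained, which drives the expected
#'   conservation-score ordering vertebrate > Neopterygian > 3R.
#' @param exon_rate_scale,repeat_rate_scale,motif_rate_scale rate scalings
#'   for exons, repeat copies and planted motif positions.
#' @param loss_prob_per_branch probability that a living element is deleted
#'   on a branch.
#' @param wgd_retention,wgd_retention_genes probability that a duplicated
#'   element (given its anchor's duplicate is retained) or gene copy
#'   survives the WGD.
#' @param inversion_rate expected inversions per branch.
#' @param inversion_length_range inversion segment length range (bp).
#' @param n_repeat_copies,repeat_length interspersed repeat family size and
#'   copy length; copies evolve slowly (young active family) so that
#'   unannotated copies exercise the copy-number filter.
#' @param repeat_annotated_frac fraction of repeat copies present in the
#'   emitted repeat annotation (the remainder emulate unannotated repeats).
#' @param motif,motif_frac consensus motif planted centrally in a fraction of
#'   elements at birth.
#' @param ancestral_target_frac fraction of gained (Neopterygian/3R) elements
#'   anchored near ancestral-target genes rather than novel anchors.
#' @param indel_rate expected neutral indels per bp per substitution/site;
#'   0 (default) keeps cohorts substitution-only so that true alignments are
#'   exact position maps.
#' @param indel_length_range neutral indel length range (bp).
#' @param divergence_events data frame (`elem_id`, `branch`) forcing an
#'   element to evolve neutrally on one branch (gain-by-divergence scenario).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tree_newick = paste0(
                         "(vert_out:0.7,(gar:0.55,((zeb:0.4,tet:0.4)c1:0.05,",
                         "(til:0.42,(fugu:0.38,seab:0.38)fs:0.04)c2:0.05)",
                         "tel:0.15)neo:0.1)root;"),
                       clade1 = c("zeb", "tet"),
                       clade2 = c("til", "fugu", "seab"),
                       outgroup_ids = "gar",
                       vertebrate_ids = "vert_out",
                       wgd_branch = "tel",
                       birth_nodes = list(vertebrate = "root",
                                          neopterygian = "neo", `3R` = "tel"),
                       n_chrom = 4L, chrom_length = 600000L,
                       n_genes = 200L, exons_per_gene = 4L,
                       exon_length = 150L, intron_length = 400L,
                       n_anchor_ancestral = 12L, n_anchor_novel = 4L,
                       n_pre_wgd_pairs = 3L, anchor_clearance = 15000L,
                       element_offset_range = c(200L, 900L),
                       n_cne_vertebrate = 30L, n_cne_neopterygian = 32L,
                       n_cne_3r = 58L,
                       cne_length_range = c(150L, 300L),
                       cne_rate_scale = c(vertebrate = 0.06,
                                          neopterygian = 0.10, `3R` = 0.14),
                       exon_rate_scale = 0.15, repeat_rate_scale = 0.05,
                       motif_rate_scale = 0.02,
                       loss_prob_per_branch = 0.05,
                       wgd_retention = 0.25, wgd_retention_genes = 0.3,
                       inversion_rate = 0.5,
                       inversion_length_range = c(30000L, 150000L),
                       n_repeat_copies = 30L, repeat_length = 400L,
                       repeat_annotated_frac = 0.7,
                       motif = "TAATTA", motif_frac = 0.2,
                       ancestral_target_frac = 0.85,
                       indel_rate = 0, indel_length_range = c(1L, 10L),
                       divergence_events = NULL) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("loss_prob_per_branch", "wgd_retention",
                             "wgd_retention_genes", "repeat_annotated_frac",
                             "motif_frac", "ancestral_target_frac")]) >= 0),
            all(unlist(cfg[c("loss_prob_per_branch", "wgd_retention",
                             "wgd_retention_genes", "repeat_annotated_frac",
                             "motif_frac", "ancestral_target_frac")]) <= 1),
            all(cne_rate_scale > 0), all(cne_rate_scale <= 1),
            n_cne_vertebrate >= 0, n_cne_neopterygian >= 0, n_cne_3r >= 0,
            n_cne_vertebrate >= 2 * n_pre_wgd_pairs)
  structure(cfg, class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

random_dna_chars <- function(n) sample(.BASES, n, replace = TRUE)

# Jukes-Cantor substitution of a character vector; rates is a per-site scale.
.mutate_chars <- function(chars, branch_length, rates) {
  if (branch_length <= 0) return(chars)
  p <- 0.75 * (1 - exp(-4 / 3 * branch_length * rates))
  hit <- which(runif(length(chars)) < p)
  hit <- hit[chars[hit] %in% .BASES]
  if (!length(hit)) return(chars)
  cur <- match(chars[hit], .BASES)
  chars[hit] <- .BASES[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
  chars
}

#' Evolve a sequence under Jukes-Cantor substitution
#'
#' Each site mutates independently with probability
#' `p = 3/4 * (1 - exp(-4/3 * branch_length * scale))`; non-ACGT sites are
#' left unchanged. Deterministic given `seed`.
#'
#' @param seq nucleotide string.
#' @param branch_length expected substitutions/site (>= 0).
#' @param rate_scale_by_region optional data frame with `start`, `end`
#'   (0-based half-open) and `scale` in (0, 1]; unlisted positions use 1.
#' @param seed RNG seed.
#' @return mutated sequence string.
#' @export
evolve_sequence <- function(seq, branch_length, rate_scale_by_region = NULL,
                            seed = 1L) {
  stopifnot(branch_length >= 0)
  chars <- strsplit(seq, "")[[1]]
  rates <- rep(1, length(chars))
  if (!is.null(rate_scale_by_region) && nrow(rate_scale_by_region)) {
    stopifnot(all(rate_scale_by_region$scale > 0),
              all(rate_scale_by_region$scale <= 1))
    for (i in seq_len(nrow(rate_scale_by_region)))
      rates[(rate_scale_by_region$start[i] + 1L):rate_scale_by_region$end[i]] <-
        rate_scale_by_region$scale[i]
  }
  paste(with_seed(seed, .mutate_chars(chars, branch_length, rates)),
        collapse = "")
}

# ---- root genome construction ------------------------------------------------

# sample a placement start for a feature of length len from free space,
# removing [start - clearance, start + len + clearance) afterwards
.place <- function(free, len, clearance = 0L) {
  w <- IRanges::width(free) - len
  ok <- which(w >= 1)
  if (!length(ok)) return(list(start = NA_integer_, free = free))
  gi <- ok[sample.int(length(ok), 1L, prob = w[ok])]
  start <- IRanges::start(free)[gi] - 1L +
    sample.int(w[gi], 1L)  # 0-based start within the gap
  used <- IRanges::IRanges(max(1L, start + 1L - clearance), start + len + clearance)
  list(start = start, free = IRanges::setdiff(free, used))
}

.build_root <- function(cfg) {
  chroms <- lapply(seq_len(cfg$n_chrom),
                   function(i) random_dna_chars(cfg$chrom_length))
  names(chroms) <- paste0("chr", seq_len(cfg$n_chrom))
  gene_span <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
  n_anchor <- cfg$n_anchor_ancestral + cfg$n_anchor_novel + 2L * cfg$n_pre_wgd_pairs
  if (cfg$n_genes == 0L || n_anchor == 0L) return(.build_root_genefree(cfg, chroms))
  # anchors spaced evenly per chromosome with jitter
  anchors_per_chrom <- rep(floor(n_anchor / cfg$n_chrom), cfg$n_chrom)
  extra <- n_anchor - sum(anchors_per_chrom)
  if (extra > 0) anchors_per_chrom[seq_len(extra)] <- anchors_per_chrom[seq_len(extra)] + 1L
  anchor_pos <- list()
  for (ci in seq_len(cfg$n_chrom)) {
    k <- anchors_per_chrom[ci]
    if (k == 0) next
    centers <- round(seq(0.5, k - 0.5, by = 1) / k * (cfg$chrom_length - 80000L)) + 40000L
    centers <- centers + round(runif(k, -8000, 8000))
    anchor_pos[[ci]] <- data.frame(chrom = names(chroms)[ci],
                                   start = as.integer(centers), stringsAsFactors = FALSE)
  }
  anchor_pos <- do.call(rbind, anchor_pos)
  anchor_pos <- anchor_pos[sample.int(nrow(anchor_pos)), , drop = FALSE]
  roles <- c(rep("anchor_ancestral", cfg$n_anchor_ancestral),
             rep("anchor_novel", cfg$n_anchor_novel),
             rep("anchor_pair", 2L * cfg$n_pre_wgd_pairs))
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_anchor)),
                      chrom = anchor_pos$chrom, start = anchor_pos$start,
                      end = anchor_pos$start + gene_span,
                      strand = sample(c("+", "-"), n_anchor, replace = TRUE),
                      role = roles, pair_partner = NA_character_, copy = "a",
                      stringsAsFactors = FALSE)
  if (cfg$n_pre_wgd_pairs > 0) {
    pidx <- which(genes$role == "anchor_pair")
    for (p in seq_len(cfg$n_pre_wgd_pairs)) {
      a <- pidx[2 * p - 1]; b <- pidx[2 * p]
      genes$pair_partner[a] <- genes$gene_id[b]
      genes$pair_partner[b] <- genes$gene_id[a]
    }
  }
  # background genes keep clear of anchor neighbourhoods
  free <- lapply(names(chroms), function(chr) {
    ir <- IRanges::IRanges(2000L, cfg$chrom_length - 2000L - gene_span)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g))
      ir <- IRanges::setdiff(ir, IRanges::IRanges(
        pmax(1L, g$start - cfg$anchor_clearance),
        g$end + cfg$anchor_clearance))
    ir
  })
  names(free) <- names(chroms)
  n_bg <- cfg$n_genes - n_anchor
  stopifnot(n_bg >= 0)
  bg <- list()
  for (i in seq_len(n_bg)) {
    chr <- sample(names(chroms), 1L)
    pl <- .place(free[[chr]], gene_span, 2000L)
    if (is.na(pl$start)) next
    free[[chr]] <- pl$free
    bg[[length(bg) + 1L]] <- data.frame(
      gene_id = sprintf("g%03d", n_anchor + length(bg) + 1L), chrom = chr,
      start = pl$start, end = pl$start + gene_span,
      strand = sample(c("+", "-"), 1L), role = "background",
      pair_partner = NA_character_, copy = "a", stringsAsFactors = FALSE)
  }
  genes <- rbind(genes, do.call(rbind, bg))
  genes$orthogroup <- paste0("OG_", genes$gene_id)
  # exons
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    off <- (seq_len(cfg$exons_per_gene) - 1L) * (cfg$exon_length + cfg$intron_length)
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = genes$start[i] + off, end = genes$start[i] + off + cfg$exon_length,
               strand = genes$strand[i], copy = "a", stringsAsFactors = FALSE)
  }))
  # elements around anchors
  age_counts <- c(vertebrate = cfg$n_cne_vertebrate - 2L * cfg$n_pre_wgd_pairs,
                  neopterygian = cfg$n_cne_neopterygian, `3R` = cfg$n_cne_3r)
  anc <- genes$gene_id[genes$role == "anchor_ancestral"]
  nov <- genes$gene_id[genes$role == "anchor_novel"]
  pair_genes <- genes$gene_id[genes$role == "anchor_pair"]
  assign_anchor <- function(age, n) {
    if (n == 0) return(character(0))
    if (age == "vertebrate") return(sample(rep_len(anc, n)))
    n_anc <- round(cfg$ancestral_target_frac * n)
    pool_novel <- switch(age,
                         neopterygian = nov[seq_len(max(1, floor(length(nov) / 2)))],
                         `3R` = nov[-seq_len(max(1, floor(length(nov) / 2)))])
    c(sample(rep_len(anc, n_anc)), sample(rep_len(pool_novel, n - n_anc)))
  }
  elem <- list()
  counter <- 0L
  prefix <- c(vertebrate = "V", neopterygian = "N", `3R` = "R")
  for (age in names(age_counts)) {
    anchors <- assign_anchor(age, age_counts[[age]])
    for (g in anchors) {
      counter <- counter + 1L
      elem[[counter]] <- list(id = sprintf("cne_%s%03d", prefix[[age]], counter),
                              age = age, anchor = g)
    }
  }
  # pre-WGD pair elements (vertebrate age, identical starting sequence)
  pair_elem <- list()
  for (p in seq_len(cfg$n_pre_wgd_pairs)) {
    ga <- pair_genes[2 * p - 1]; gb <- pair_genes[2 * p]
    counter <- counter + 1L
    ida <- sprintf("cne_P%03d", counter)
    elem[[counter]] <- list(id = ida, age = "vertebrate", anchor = ga)
    counter <- counter + 1L
    idb <- sprintf("cne_P%03d", counter)
    elem[[counter]] <- list(id = idb, age = "vertebrate", anchor = gb)
    pair_elem[[p]] <- c(ida, idb)
  }
  # lay elements out on alternating sides of their anchor; per-element gaps
  # keep the whole cluster well inside the anchor clearance, so the anchor is
  # always each element's nearest gene
  lens <- sample(seq(cfg$cne_length_range[1], cfg$cne_length_range[2]),
                 length(elem), replace = TRUE)
  placed <- list()
  by_anchor <- split(seq_along(elem), vapply(elem, `[[`, "", "anchor"))
  for (g in names(by_anchor)) {
    idxs <- by_anchor[[g]]
    grow <- genes[genes$gene_id == g, ]
    side <- rep_len(c(1L, -1L), length(idxs))
    gaps <- round(runif(length(idxs), cfg$element_offset_range[1],
                        cfg$element_offset_range[2]))
    pos_left <- grow$start; pos_right <- grow$end
    for (k in seq_along(idxs)) {
      L <- lens[idxs[k]]
      if (side[k] > 0) {
        s <- pos_right + gaps[k]
        pos_right <- s + L
      } else {
        s <- pos_left - gaps[k] - L
        pos_left <- s
      }
      placed[[idxs[k]]] <- data.frame(
        elem_id = elem[[idxs[k]]]$id, ancestral_id = elem[[idxs[k]]]$id,
        chrom = grow$chrom, start = as.integer(s), end = as.integer(s + L),
        strand = "+", age = elem[[idxs[k]]]$age,
        target_gene = g, copy = "a", stringsAsFactors = FALSE)
    }
  }
  elements <- do.call(rbind, placed)
  elements$born <- FALSE  # births happen at the configured nodes
  elements$motif <- runif(nrow(elements)) < cfg$motif_frac
  stopifnot(all(elements$start >= 0), all(elements$end <= cfg$chrom_length))
  # identical starting sequence for pre-WGD pair elements
  for (p in seq_along(pair_elem)) {
    ia <- which(elements$elem_id == pair_elem[[p]][1])
    ib <- which(elements$elem_id == pair_elem[[p]][2])
    La <- elements$end[ia] - elements$start[ia]
    elements$end[ib] <- elements$start[ib] + La  # same length
    chroms[[elements$chrom[ib]]][(elements$start[ib] + 1L):elements$end[ib]] <-
      chroms[[elements$chrom[ia]]][(elements$start[ia] + 1L):elements$end[ia]]
  }
  # interspersed repeats
  rep_seq <- random_dna_chars(cfg$repeat_length)
  occupied <- rbind(genes[c("chrom", "start", "end")],
                    elements[c("chrom", "start", "end")])
  free <- lapply(names(chroms), function(chr) {
    ir <- IRanges::IRanges(1000L, cfg$chrom_length - 1000L - cfg$repeat_length)
    occ <- occupied[occupied$chrom == chr, , drop = FALSE]
    if (nrow(occ))
      ir <- IRanges::setdiff(ir, IRanges::IRanges(pmax(1L, occ$start - 500L),
                                                  occ$end + 500L))
    ir
  })
  names(free) <- names(chroms)
  reps <- list()
  for (i in seq_len(cfg$n_repeat_copies)) {
    chr <- sample(names(chroms), 1L)
    pl <- .place(free[[chr]], cfg$repeat_length, 500L)
    if (is.na(pl$start)) next
    free[[chr]] <- pl$free
    chroms[[chr]][(pl$start + 1L):(pl$start + cfg$repeat_length)] <- rep_seq
    reps[[length(reps) + 1L]] <- data.frame(
      rep_id = sprintf("rep%03d", length(reps) + 1L), chrom = chr,
      start = pl$start, end = pl$start + cfg$repeat_length, strand = "+",
      annotated = runif(1) < cfg$repeat_annotated_frac, copy = "a",
      stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, reps)
  # the layout must be collision-free or downstream bookkeeping breaks
  occ_all <- rbind(genes[c("chrom", "start", "end")],
                   elements[c("chrom", "start", "end")],
                   repeats[c("chrom", "start", "end")])
  for (chr in unique(occ_all$chrom)) {
    oc <- occ_all[occ_all$chrom == chr, , drop = FALSE]
    oc <- oc[order(oc$start), , drop = FALSE]
    if (nrow(oc) > 1 && any(oc$start[-1] < oc$end[-nrow(oc)]))
      stop("config error: planted features collide on ", chr,
           "; increase chrom_length or reduce anchors/elements")
  }
  pair_df <- if (length(pair_elem))
    data.frame(a = vapply(pair_elem, `[`, "", 1), b = vapply(pair_elem, `[`, "", 2),
               origin = "2R", stringsAsFactors = FALSE)
  else data.frame(a = character(), b = character(), origin = character(),
                  stringsAsFactors = FALSE)
  list(chroms = chroms, genes = genes, exons = exons, repeats = repeats,
       elements = elements, losses = data.frame(branch = character(),
                                                elem_id = character(),
                                                stringsAsFactors = FALSE),
       paralog_elem_pairs = pair_df)
}

# degenerate layout without genes: elements and repeats in free space, no
# target truth
.build_root_genefree <- function(cfg, chroms) {
  stopifnot(cfg$n_pre_wgd_pairs == 0L)
  genes <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      role = character(), pair_partner = character(),
                      copy = character(), orthogroup = character(),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      copy = character(), stringsAsFactors = FALSE)
  free <- lapply(names(chroms), function(chr)
    IRanges::IRanges(2000L, cfg$chrom_length - 2000L))
  names(free) <- names(chroms)
  counts <- c(vertebrate = cfg$n_cne_vertebrate,
              neopterygian = cfg$n_cne_neopterygian, `3R` = cfg$n_cne_3r)
  prefix <- c(vertebrate = "V", neopterygian = "N", `3R` = "R")
  placed <- list()
  k <- 0L
  for (age in names(counts)) for (i in seq_len(counts[[age]])) {
    k <- k + 1L
    L <- sample(seq(cfg$cne_length_range[1], cfg$cne_length_range[2]), 1L)
    chr <- sample(names(chroms), 1L)
    pl <- .place(free[[chr]], L, 200L)
    if (is.na(pl$start)) next
    free[[chr]] <- pl$free
    placed[[k]] <- data.frame(
      elem_id = sprintf("cne_%s%03d", prefix[[age]], k),
      ancestral_id = sprintf("cne_%s%03d", prefix[[age]], k),
      chrom = chr, start = pl$start, end = pl$start + L, strand = "+",
      age = age, target_gene = NA_character_, copy = "a",
      stringsAsFactors = FALSE)
  }
  elements <- do.call(rbind, placed)
  elements$born <- FALSE
  elements$motif <- runif(nrow(elements)) < cfg$motif_frac
  rep_seq <- random_dna_chars(cfg$repeat_length)
  reps <- list()
  for (i in seq_len(cfg$n_repeat_copies)) {
    chr <- sample(names(chroms), 1L)
    pl <- .place(free[[chr]], cfg$repeat_length, 500L)
    if (is.na(pl$start)) next
    free[[chr]] <- pl$free
    chroms[[chr]][(pl$start + 1L):(pl$start + cfg$repeat_length)] <- rep_seq
    reps[[length(reps) + 1L]] <- data.frame(
      rep_id = sprintf("rep%03d", length(reps) + 1L), chrom = chr,
      start = pl$start, end = pl$start + cfg$repeat_length, strand = "+",
      annotated = runif(1) < cfg$repeat_annotated_frac, copy = "a",
      stringsAsFactors = FALSE)
  }
  repeats <- if (length(reps)) do.call(rbind, reps) else
    data.frame(rep_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), annotated = logical(),
               copy = character(), stringsAsFactors = FALSE)
  list(chroms = chroms, genes = genes, exons = exons, repeats = repeats,
       elements = elements,
       losses = data.frame(branch = character(), elem_id = character(),
                           stringsAsFactors = FALSE),
       paralog_elem_pairs = data.frame(a = character(), b = character(),
                                       origin = character(),
                                       stringsAsFactors = FALSE))
}

.plant_motif <- function(chroms, e, motif) {
  ml <- nchar(motif)
  mid <- e$start + ((e$end - e$start) - ml) %/% 2L
  chroms[[e$chrom]][(mid + 1L):(mid + ml)] <- strsplit(motif, "")[[1]]
  chroms
}

# ---- structural operators ----------------------------------------------------

.feature_tables <- c("genes", "exons", "repeats", "elements")

.shift_features <- function(state, chrom, from, by) {
  for (tb in .feature_tables) {
    df <- state[[tb]]
    sel <- df$chrom == chrom & df$start >= from
    df$start[sel] <- df$start[sel] + by
    df$end[sel] <- df$end[sel] + by
    state[[tb]] <- df
  }
  state
}

# delete [s, e) from a chromosome; features wholly inside are dropped
.delete_span <- function(state, chrom, s, e) {
  for (tb in .feature_tables) {
    df <- state[[tb]]
    inside <- df$chrom == chrom & df$start >= s & df$end <= e
    straddle <- df$chrom == chrom & !inside & df$start < e & df$end > s
    if (any(straddle)) stop("internal error: deletion straddles a feature")
    state[[tb]] <- df[!inside, , drop = FALSE]
  }
  state$chroms[[chrom]] <- state$chroms[[chrom]][-((s + 1L):e)]
  .shift_features(state, chrom, e, -(e - s))
}

.invert_segment <- function(state, chrom, s, e) {
  seg <- state$chroms[[chrom]][(s + 1L):e]
  comp <- chartr("ACGT", "TGCA", paste(rev(seg), collapse = ""))
  state$chroms[[chrom]][(s + 1L):e] <- strsplit(comp, "")[[1]]
  for (tb in .feature_tables) {
    df <- state[[tb]]
    sel <- df$chrom == chrom & df$start >= s & df$end <= e
    if (any(sel)) {
      ns <- s + (e - df$end[sel]); ne <- s + (e - df$start[sel])
      df$start[sel] <- ns; df$end[sel] <- ne
      df$strand[sel] <- ifelse(df$strand[sel] == "+", "-", "+")
      state[[tb]] <- df
    }
  }
  state
}

# feature-free gap positions on a chromosome (for breakpoints)
.free_positions <- function(state, chrom, pad = 50L) {
  L <- length(state$chroms[[chrom]])
  occ <- do.call(rbind, lapply(.feature_tables, function(tb) {
    df <- state[[tb]]
    df[df$chrom == chrom, c("start", "end"), drop = FALSE]
  }))
  ir <- IRanges::IRanges(1L, L)
  if (nrow(occ))
    ir <- IRanges::setdiff(ir, IRanges::IRanges(pmax(1L, occ$start + 1L - pad),
                                                pmin(L, occ$end + pad)))
  ir
}

.apply_inversions <- function(state, cfg) {
  n <- rpois(1L, cfg$inversion_rate)
  for (i in seq_len(n)) {
    chrom <- sample(names(state$chroms), 1L)
    free <- .free_positions(state, chrom)
    if (!length(free)) next
    len <- round(runif(1, cfg$inversion_length_range[1], cfg$inversion_length_range[2]))
    pos <- sort(unlist(lapply(seq_along(free), function(j)
      IRanges::start(free)[j]:IRanges::end(free)[j])))
    s_cands <- pos[pos + len <= length(state$chroms[[chrom]])]
    ok <- FALSE
    for (try in seq_len(20L)) {
      if (!length(s_cands)) break
      s <- sample(s_cands, 1L) - 1L
      e <- s + len
      if (length(IRanges::findOverlaps(IRanges::IRanges(e, e), free)) > 0) {
        ok <- TRUE; break
      }
    }
    if (ok) state <- .invert_segment(state, chrom, s, e)
  }
  state
}

.apply_wgd <- function(state, cfg) {
  base_chroms <- names(state$chroms)
  for (chr in base_chroms) {
    nb <- paste0(chr, "b")
    state$chroms[[nb]] <- state$chroms[[chr]]
    for (tb in .feature_tables) {
      df <- state[[tb]]
      dup <- df[df$chrom == chr, , drop = FALSE]
      if (!nrow(dup)) next
      dup$chrom <- nb
      dup$copy <- "b"
      if (tb == "genes") {
        dup$pair_partner <- ifelse(is.na(dup$pair_partner), NA,
                                   paste0(dup$pair_partner, "_b"))
        dup$gene_id <- paste0(dup$gene_id, "_b")
      }
      if (tb == "exons") dup$gene_id <- paste0(dup$gene_id, "_b")
      if (tb == "repeats") dup$rep_id <- paste0(dup$rep_id, "_b")
      if (tb == "elements") {
        dup <- dup[dup$born, , drop = FALSE]  # unborn loci are not duplicated
        if (nrow(dup)) {
          dup$elem_id <- paste0(dup$elem_id, "_b")
          dup$target_gene <- ifelse(is.na(dup$target_gene), NA,
                                    paste0(dup$target_gene, "_b"))
        }
      }
      state[[tb]] <- rbind(df, dup)
    }
  }
  # retention: pre-WGD pair anchors always revert to single copy, so each gene
  # carries at most one paralogy relation class
  bgenes <- state$genes[state$genes$copy == "b", , drop = FALSE]
  keep_gene <- runif(nrow(bgenes)) < cfg$wgd_retention_genes
  keep_gene[bgenes$role == "anchor_pair"] <- FALSE
  gene_kept <- setNames(keep_gene, bgenes$gene_id)
  belem <- state$elements[state$elements$copy == "b", , drop = FALSE]
  keep_elem <- runif(nrow(belem)) < cfg$wgd_retention
  # an element duplicate survives only alongside its anchor's duplicate
  anchored <- !is.na(belem$target_gene)
  keep_elem[anchored] <- keep_elem[anchored] &
    unname(gene_kept[belem$target_gene[anchored]])
  elem_kept <- setNames(keep_elem, belem$elem_id)
  # record retained duplicate element pairs
  kept_ids <- names(elem_kept)[elem_kept]
  if (length(kept_ids)) {
    state$paralog_elem_pairs <- rbind(
      state$paralog_elem_pairs,
      data.frame(a = sub("_b$", "", kept_ids), b = kept_ids, origin = "3R",
                 stringsAsFactors = FALSE))
  }
  # deletions, applied right-to-left per chromosome
  dels <- rbind(
    data.frame(chrom = bgenes$chrom, start = bgenes$start, end = bgenes$end,
               gene = bgenes$gene_id, stringsAsFactors = FALSE)[!keep_gene, ],
    data.frame(chrom = belem$chrom, start = belem$start, end = belem$end,
               gene = NA, stringsAsFactors = FALSE)[!keep_elem, ])
  dels <- dels[order(dels$chrom, -dels$start), , drop = FALSE]
  for (i in seq_len(nrow(dels))) {
    if (!is.na(dels$gene[i])) {
      # drop the gene's exons first so the span deletion is clean
      state$exons <- state$exons[state$exons$gene_id != dels$gene[i], , drop = FALSE]
    }
    state <- .delete_span(state, dels$chrom[i], dels$start[i], dels$end[i])
  }
  state
}

.apply_losses <- function(state, branch, cfg) {
  born <- which(state$elements$born)
  lost <- born[runif(length(born)) < cfg$loss_prob_per_branch]
  if (!length(lost)) return(state)
  ids <- state$elements$elem_id[lost]
  dels <- state$elements[lost, c("chrom", "start", "end"), drop = FALSE]
  dels <- dels[order(dels$chrom, -dels$start), , drop = FALSE]
  for (i in seq_len(nrow(dels)))
    state <- .delete_span(state, dels$chrom[i], dels$start[i], dels$end[i])
  state$losses <- rbind(state$losses,
                        data.frame(branch = branch, elem_id = ids,
                                   stringsAsFactors = FALSE))
  state
}

.apply_births <- function(state, node, cfg) {
  ages <- names(cfg$birth_nodes)[vapply(cfg$birth_nodes, identical, TRUE, node)]
  if (!length(ages)) return(state)
  sel <- which(!state$elements$born & state$elements$age %in% ages &
                 state$elements$copy == "a")
  if (!length(sel)) return(state)
  state$elements$born[sel] <- TRUE
  for (i in sel[state$elements$motif[sel]])
    state$chroms <- .plant_motif(state$chroms, state$elements[i, ], cfg$motif)
  state
}

.apply_indels <- function(state, branch_len, cfg) {
  if (cfg$indel_rate <= 0) return(state)
  for (chrom in names(state$chroms)) {
    n <- rpois(1L, cfg$indel_rate * branch_len * length(state$chroms[[chrom]]))
    for (i in seq_len(n)) {
      free <- .free_positions(state, chrom, pad = 20L)
      if (!length(free)) break
      len <- sample(seq(cfg$indel_length_range[1], cfg$indel_length_range[2]), 1L)
      gi <- sample.int(length(free), 1L, prob = IRanges::width(free))
      pos <- IRanges::start(free)[gi] - 1L +
        sample.int(max(1L, IRanges::width(free)[gi] - len), 1L)
      if (runif(1) < 0.5) {
        e <- min(pos + len, IRanges::end(free)[gi])
        if (e > pos) state <- .delete_span(state, chrom, pos, e)
      } else {
        ins <- random_dna_chars(len)
        state$chroms[[chrom]] <- append(state$chroms[[chrom]], ins, after = pos)
        state <- .shift_features(state, chrom, pos, len)
      }
    }
  }
  state
}

.substitute_branch <- function(state, branch_len, branch, cfg) {
  if (branch_len <= 0) return(state)
  div <- cfg$divergence_events
  for (chrom in names(state$chroms)) {
    L <- length(state$chroms[[chrom]])
    rates <- rep(1, L)
    ex <- state$exons[state$exons$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(ex)))
      rates[(ex$start[i] + 1L):ex$end[i]] <- cfg$exon_rate_scale
    rp <- state$repeats[state$repeats$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(rp)))
      rates[(rp$start[i] + 1L):rp$end[i]] <- cfg$repeat_rate_scale
    el <- state$elements[state$elements$chrom == chrom & state$elements$born, ,
                         drop = FALSE]
    for (i in seq_len(nrow(el))) {
      sc <- cfg$cne_rate_scale[[el$age[i]]]
      if (!is.null(div) && nrow(div) &&
          any(div$elem_id == el$elem_id[i] & div$branch == branch)) sc <- 1
      rates[(el$start[i] + 1L):el$end[i]] <- sc
      if (el$motif[i] && sc < 1) {
        ml <- nchar(cfg$motif)
        mid <- el$start[i] + ((el$end[i] - el$start[i]) - ml) %/% 2L
        rates[(mid + 1L):(mid + ml)] <- cfg$motif_rate_scale
      }
    }
    state$chroms[[chrom]] <- .mutate_chars(state$chroms[[chrom]], branch_len, rates)
  }
  state
}

# ---- cohort simulation -------------------------------------------------------

#' Simulate a multi-species genome cohort with planted CNEs
#'
#' Builds the root genome, walks the species tree applying (in order, per
#' branch) whole-genome duplication, element births, element losses,
#' inversions, neutral indels and Jukes-Cantor substitution, and returns the
#' leaf genomes together with complete ground truth. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, per-species FASTA/BED/GFF3,
#'   the species tree, the orthology table and the truth tables are written
#'   there.
#' @return list of class `sim_cohort` with `genomes` ([genome_set()]),
#'   `tree` ([species_tree()]), `orthology`, `truth` (per-species element
#'   table, loss events, paralog element pairs, vCNE-analog target
#'   orthogroups) and `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  phy <- ape::read.tree(text = config$tree_newick)
  if (is.null(phy)) stop("config error: unparseable tree")
  labels <- c(phy$tip.label, phy$node.label)
  if (!(config$wgd_branch %in% labels))
    stop("config error: wgd_branch not a node of the tree")
  # wgd must sit on the path to the teleost clades
  res <- with_seed(config$seed, {
    root_state <- .build_root(config)
    leaves <- list()
    walk <- function(state, node_num) {
      node_lab <- if (node_num <= length(phy$tip.label)) phy$tip.label[node_num]
      else phy$node.label[node_num - length(phy$tip.label)]
      kids <- phy$edge[phy$edge[, 1] == node_num, 2]
      if (!length(kids)) {
        leaves[[node_lab]] <<- state
        return(invisible(NULL))
      }
      for (kid in kids) {
        blen <- phy$edge.length[phy$edge[, 1] == node_num & phy$edge[, 2] == kid]
        kid_lab <- if (kid <= length(phy$tip.label)) phy$tip.label[kid]
        else phy$node.label[kid - length(phy$tip.label)]
        st <- state
        if (identical(kid_lab, config$wgd_branch)) st <- .apply_wgd(st, config)
        st <- .apply_births(st, kid_lab, config)
        st <- .apply_losses(st, kid_lab, config)
        st <- .apply_inversions(st, config)
        st <- .apply_indels(st, blen, config)
        st <- .substitute_branch(st, blen, kid_lab, config)
        walk(st, kid)
      }
    }
    root_num <- length(phy$tip.label) + 1L
    root_lab <- phy$node.label[1]
    root_state <- .apply_births(root_state, root_lab, config)
    walk(root_state, root_num)
    leaves
  })
  # assemble outputs
  species <- phy$tip.label
  gs_in <- lapply(species, function(sp) {
    st <- res[[sp]]
    seqs <- vapply(st$chroms, paste, character(1), collapse = "")
    exons <- data.frame(chrom = st$exons$chrom, start = st$exons$start,
                        end = st$exons$end, strand = st$exons$strand,
                        gene_id = st$exons$gene_id, stringsAsFactors = FALSE)
    reps <- st$repeats[st$repeats$annotated, , drop = FALSE]
    repeats <- data.frame(chrom = reps$chrom, start = reps$start, end = reps$end,
                          strand = reps$strand, stringsAsFactors = FALSE)
    genes <- data.frame(chrom = st$genes$chrom, start = st$genes$start,
                        end = st$genes$end, strand = st$genes$strand,
                        gene_id = st$genes$gene_id, stringsAsFactors = FALSE)
    list(sequences = seqs, exons = exons, repeats = repeats, genes = genes)
  })
  names(gs_in) <- species
  genomes <- genome_set(gs_in)
  tree <- species_tree(phy, config$clade1, config$clade2,
                       config$outgroup_ids, config$vertebrate_ids)
  # orthology table (per species)
  ortho <- do.call(rbind, lapply(species, function(sp) {
    g <- res[[sp]]$genes
    if (nrow(g) == 0)
      return(data.frame(species_id = character(), gene_id = character(),
                        orthogroup_id = character(),
                        paralog_partner_ids = character(),
                        paralog_origin = character(), stringsAsFactors = FALSE))
    partners <- character(nrow(g))
    origin <- rep("none", nrow(g))
    is_b <- g$copy == "b"
    has_b <- paste0(g$gene_id, "_b") %in% g$gene_id
    partners[is_b] <- sub("_b$", "", g$gene_id[is_b])
    origin[is_b] <- "post-WGD"
    partners[has_b] <- paste0(g$gene_id[has_b], "_b")
    origin[has_b] <- "post-WGD"
    pre <- !is.na(g$pair_partner) & g$pair_partner %in% g$gene_id
    partners[pre] <- g$pair_partner[pre]
    origin[pre] <- "pre-WGD"
    data.frame(species_id = sp, gene_id = g$gene_id,
               orthogroup_id = g$orthogroup, paralog_partner_ids = partners,
               paralog_origin = origin, stringsAsFactors = FALSE)
  }))
  # truth tables
  elems <- do.call(rbind, lapply(species, function(sp) {
    e <- res[[sp]]$elements
    e <- e[e$born, , drop = FALSE]
    data.frame(species_id = sp, elem_id = e$elem_id, ancestral_id = e$ancestral_id,
               chrom = e$chrom, start = e$start, end = e$end, strand = e$strand,
               age = e$age, motif = e$motif, target_gene = e$target_gene,
               stringsAsFactors = FALSE)
  }))
  losses <- unique(do.call(rbind, lapply(species, function(sp) res[[sp]]$losses)))
  pairs <- unique(do.call(rbind, lapply(species,
                                        function(sp) res[[sp]]$paralog_elem_pairs)))
  vert_anchors <- unique(elems$target_gene[elems$age == "vertebrate"])
  vert_anchors <- sub("_b$", "", vert_anchors[!is.na(vert_anchors)])
  vcne_ogs <- unique(paste0("OG_", vert_anchors))
  truth <- list(elements = elems, losses = losses, paralog_pairs = pairs,
                vcne_target_orthogroups = vcne_ogs)
  cohort <- structure(list(genomes = genomes, tree = tree, orthology = ortho,
                           truth = truth, config = config),
                      class = "sim_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", length(x$genomes), "species, seed", x$config$seed, "\n")
  cat("  planted elements:",
      length(unique(x$truth$elements$ancestral_id)), "ancestral ids;",
      nrow(x$truth$losses), "loss event(s);",
      nrow(x$truth$paralog_pairs), "paralog pair(s)\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits per-species FASTA/BED/GFF3 via [write_genome()], the species tree
#' (newick), clade designations (TSV), the orthology table and the truth
#' tables (TSV).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(cohort$genomes)) write_genome(cohort$genomes, sp, dir)
  ape::write.tree(cohort$tree$phylo, file.path(dir, "tree.nwk"))
  clades <- rbind(
    data.frame(species_id = cohort$tree$clade1, set = "clade1"),
    data.frame(species_id = cohort$tree$clade2, set = "clade2"),
    data.frame(species_id = cohort$tree$outgroup_ids, set = "outgroup"),
    data.frame(species_id = cohort$tree$vertebrate_ids, set = "vertebrate"))
  write.table(clades, file.path(dir, "clades.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_orthology(cohort$orthology, file.path(dir, "orthology.tsv"))
  tr <- cohort$truth
  write.table(tr$elements, file.path(dir, "truth_elements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tr$losses, file.path(dir, "truth_losses.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tr$paralog_pairs, file.path(dir, "truth_paralog_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(tr$vcne_target_orthogroups,
             file.path(dir, "vcne_target_orthogroups.txt"))
  invisible(dir)
}
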