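#' Parameters for synteny-based target association
#'
#' @param window bp scanned on each side of a CNE for candidate genes.
#' @param min_synteny_species minimum number of species supporting a
#'   CNE-orthogroup pair.
#' @param n_bootstrap bootstrap replicates for the resampling null.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `assoc_params`.
#' @export
assoc_params <- function(window = 1000000L, min_synteny_species = 5L,
                         n_bootstrap = 10000L, seed = 1L) {
  stopifnot(window > 0, min_synteny_species >= 1, n_bootstrap >= 1)
  structure(list(window = as.integer(window),
                 min_synteny_species = as.integer(min_synteny_species),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "assoc_params")
}

#' Candidate genes around a CNE in every species where it is present
#'
#' A gene is a candidate when its body overlaps the window
#' `[hit_start - window, hit_end + window)`; distance is the gap in bp to
#' the gene body (0 when overlapping, e.g. for intronic elements).
#'
#' @param cne_id CNE id.
#' @param presence presence matrix.
#' @param genes_by_species named list of per-species gene tables
#'   (`chrom`, `start`, `end`, `gene_id`).
#' @param window bp on each side.
#' @return data frame `species_id`, `gene_id`, `distance`, `rank`
#'   (1-based rank by increasing distance, mean rank for ties).
#' @export
candidate_genes <- function(cne_id, presence, genes_by_species, window = 1000000L) {
  hits <- presence[presence$query_id == cne_id, , drop = FALSE]
  out <- list()
  for (j in seq_len(nrow(hits))) {
    h <- hits[j, ]
    genes <- genes_by_species[[h$species_id]]
    if (is.null(genes) || nrow(genes) == 0) next
    sel <- genes$chrom == h$chrom & genes$end > h$start - window &
      genes$start < h$end + window
    g <- genes[sel, , drop = FALSE]
    if (!nrow(g)) next
    dist <- pmax(0L, pmax(g$start - h$end, h$start - g$end))
    out[[length(out) + 1L]] <- data.frame(
      species_id = h$species_id, gene_id = g$gene_id, distance = dist,
      rank = rank(dist, ties.method = "average"), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(species_id = character(), gene_id = character(),
                      distance = integer(), rank = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Synteny scores and proximity ranks per orthogroup
#'
#' The synteny score of an orthogroup is the number of species whose
#' candidate list contains a member; the proximity rank is the mean, over
#' those species, of the member's rank when candidates are sorted by
#' increasing distance (the best-ranked member per species when the
#' orthogroup has several local members, e.g. after a WGD). Genes without an
#' orthogroup are treated as singleton orthogroups.
#'
#' @param candidates output of [candidate_genes()].
#' @param orthology orthology table (see [read_orthology()]).
#' @return data frame `orthogroup`, `score`, `proximity_rank`, `genes`.
#' @export
synteny_scores <- function(candidates, orthology) {
  if (nrow(candidates) == 0)
    return(data.frame(orthogroup = character(), score = integer(),
                      proximity_rank = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  og <- orthology$orthogroup_id[match(paste(candidates$species_id,
                                            candidates$gene_id),
                                      paste(orthology$species_id,
                                            orthology$gene_id))]
  miss <- is.na(og)
  if (any(miss)) {
    cne_log(sprintf("synteny_scores: %d candidate gene(s) without orthogroup",
                    sum(miss)), level = "debug")
    og[miss] <- paste0("singleton_", candidates$gene_id[miss])
  }
  candidates$orthogroup <- og
  per <- split(candidates, candidates$orthogroup)
  out <- lapply(per, function(d) {
    best <- vapply(split(d$rank, d$species_id), min, numeric(1))
    data.frame(orthogroup = d$orthogroup[1], score = length(best),
               proximity_rank = mean(best),
               genes = paste(sort(unique(d$gene_id)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select target orthogroups for one CNE
#'
#' Filters orthogroups supported by at least `min_synteny_species` species,
#' then keeps the maximum synteny score, then the minimum proximity rank,
#' retaining all exact ties.
#'
#' @param scored output of [synteny_scores()].
#' @param params an [assoc_params()].
#' @return data frame of selected orthogroups (possibly empty).
#' @export
select_targets <- function(scored, params = assoc_params()) {
  s <- scored[scored$score >= params$min_synteny_species, , drop = FALSE]
  if (nrow(s) == 0) return(s)
  s <- s[s$score == max(s$score), , drop = FALSE]
  s <- s[abs(s$proximity_rank - min(s$proximity_rank)) < 1e-9, , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Associate every CNE with candidate target genes
#'
#' Runs [candidate_genes()], [synteny_scores()] and [select_targets()] per
#' CNE and returns one association row per CNE.
#'
#' @param cnes CNE (or ancestral) set data frame.
#' @param presence presence matrix.
#' @param genes_by_species named list of per-species gene tables.
#' @param orthology orthology table.
#' @param params an [assoc_params()].
#' @return data frame `cne_id`, `target_orthogroups`, `target_genes`,
#'   `synteny_score`, `proximity_rank`, `n_candidates_ref`, `target_class`
#'   (`none` until classified).
#' @export
associate_cnes <- function(cnes, presence, genes_by_species, orthology,
                           params = assoc_params()) {
  out <- lapply(cnes$id, function(id) {
    cand <- candidate_genes(id, presence, genes_by_species, params$window)
    ref_sp <- cnes$ref_species[match(id, cnes$id)]
    n_ref <- sum(cand$species_id == ref_sp)
    sel <- select_targets(synteny_scores(cand, orthology), params)
    if (nrow(sel) == 0) {
      data.frame(cne_id = id, target_orthogroups = "", target_genes = "",
                 synteny_score = NA_integer_, proximity_rank = NA_real_,
                 n_candidates_ref = n_ref, target_class = "none",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cne_id = id,
                 target_orthogroups = paste(sel$orthogroup, collapse = ","),
                 target_genes = paste(unique(unlist(strsplit(sel$genes, ","))),
                                      collapse = ","),
                 synteny_score = sel$score[1], proximity_rank = sel$proximity_rank[1],
                 n_candidates_ref = n_ref, target_class = "unclassified",
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label associations as ancestral or novel targets
#'
#' An association is `ancestral` when any selected target orthogroup belongs
#' to the vertebrate-CNE target orthogroup set, else `novel`; CNEs without
#' targets stay `none`.
#'
#' @param associations output of [associate_cnes()].
#' @param vcne_target_orthogroups character vector of orthogroup ids.
#' @return `associations` with `target_class` filled in.
#' @export
classify_targets <- function(associations, vcne_target_orthogroups) {
  cls <- vapply(seq_len(nrow(associations)), function(i) {
    ogs <- strsplit(associations$target_orthogroups[i], ",")[[1]]
    ogs <- ogs[nzchar(ogs)]
    if (!length(ogs)) "none"
    else if (any(ogs %in% vcne_target_orthogroups)) "ancestral" else "novel"
  }, character(1))
  associations$target_class <- cls
  associations
}

#' Bootstrap resampling null for ancestral-target associations
#'
#' Each replicate re-draws, for every associated CNE, a random gene set of
#' the same size as its selected target list, uniformly without replacement
#' from the reference species' full gene complement, and counts CNEs whose
#' draw contains a gene from a vertebrate-CNE target orthogroup. Reports the
#' null mean, standard deviation and the z-score of the observed ancestral
#' count. Deterministic given `params$seed`.
#'
#' @param associations classified associations ([classify_targets()]).
#' @param ref_genes reference-species gene table (`gene_id`).
#' @param orthology orthology table (to map genes to orthogroups).
#' @param vcne_target_orthogroups vertebrate-CNE target orthogroup ids.
#' @param params an [assoc_params()].
#' @param ref_species reference species id (for the orthogroup lookup).
#' @return list `observed`, `mean`, `sd`, `z`, `n_bootstrap`,
#'   `degenerate` (`TRUE` when sd is 0, in which case `z` is `Inf`-signed).
#' @export
bootstrap_null <- function(associations, ref_genes, orthology,
                           vcne_target_orthogroups, params = assoc_params(),
                           ref_species = NULL) {
  assoc <- associations[associations$target_class %in% c("ancestral", "novel"), ,
                        drop = FALSE]
  observed <- sum(assoc$target_class == "ancestral")
  G <- nrow(ref_genes)
  ogs <- orthology$orthogroup_id[match(
    paste(ref_species %||% orthology$species_id[1], ref_genes$gene_id),
    paste(orthology$species_id, orthology$gene_id))]
  anc_gene <- !is.na(ogs) & ogs %in% vcne_target_orthogroups
  k_sizes <- vapply(strsplit(assoc$target_genes, ","), function(x)
    max(1L, sum(nzchar(x))), integer(1))
  counts <- with_seed(params$seed, {
    total <- numeric(params$n_bootstrap)
    for (k in sort(unique(k_sizes))) {
      nk <- sum(k_sizes == k)
      # draw nk * B subsets of size k without replacement
      hit <- matrix(FALSE, nrow = params$n_bootstrap, ncol = nk)
      for (r in seq_len(nk)) {
        if (k == 1) {
          idx <- sample.int(G, params$n_bootstrap, replace = TRUE)
          hit[, r] <- anc_gene[idx]
        } else {
          hit[, r] <- vapply(seq_len(params$n_bootstrap), function(b)
            any(anc_gene[sample.int(G, k)]), logical(1))
        }
      }
      total <- total + rowSums(hit)
    }
    total
  })
  mu <- mean(counts); sdev <- sd(counts)
  degenerate <- !is.finite(sdev) || sdev == 0
  z <- if (degenerate) sign(observed - mu) * Inf else (observed - mu) / sdev
  list(observed = observed, mean = mu, sd = sdev, z = z,
       n_bootstrap = params$n_bootstrap, degenerate = degenerate)
}
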