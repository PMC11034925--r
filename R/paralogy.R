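#' Nonself sequence hits within a CNE set
#'
#' Searches every CNE sequence against the set's own sequences (not the
#' genome, so repeat contamination cannot create spurious pairs), discards
#' hits of an element to itself, and returns a deduplicated symmetric pair
#' list. E-values use the total set length as the search space.
#'
#' @param cnes CNE set data frame.
#' @param genomes a [genome_set()] (for sequence extraction).
#' @param params a [search_params()].
#' @return data frame `a`, `b` (`a < b`), `score`, `evalue`, `identity`.
#' @export
self_hits <- function(cnes, genomes, params = search_params()) {
  seqs <- cne_sequences(cnes, genomes)
  # concatenate the set with N spacers so ids can be recovered by offset
  spacer <- strrep("N", 50L)
  offsets <- cumsum(c(0L, head(nchar(seqs) + 50L, -1L)))
  subject <- paste(seqs, collapse = spacer)
  pseudo <- list(sequences = setNames(list(subject), "cneset"))
  hits <- search_genome(seqs, pseudo, params, species_id = "self")
  if (nrow(hits) == 0)
    return(data.frame(a = character(), b = character(), score = numeric(),
                      evalue = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  # map subject position to member id
  idx <- findInterval(hits$start, offsets)
  hits$subject_id <- names(seqs)[idx]
  hits <- hits[hits$subject_id != hits$query_id, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(a = character(), b = character(), score = numeric(),
                      evalue = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  key <- paste(a, b)
  o <- order(key, hits$evalue)
  first <- !duplicated(key[o])
  out <- data.frame(a = a[o][first], b = b[o][first],
                    score = hits$score[o][first],
                    evalue = hits$evalue[o][first],
                    identity = hits$identity[o][first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# origin of the paralogy relation between two genes of one species, from the
# orthology table; NA when the genes are not annotated paralogs
.pair_origin <- function(orthology, species, g1, g2) {
  row <- orthology[orthology$species_id == species & orthology$gene_id == g1, ]
  if (nrow(row) == 0) return(NA_character_)
  partners <- strsplit(row$paralog_partner_ids[1], ",")[[1]]
  if (!(g2 %in% partners)) return(NA_character_)
  row$paralog_origin[1]
}

#' Group duplicated CNEs into paralogy clusters
#'
#' A nonself-hit pair becomes an edge only when the two elements' selected
#' target genes are the same gene or annotated paralogs; clusters are the
#' connected components of kept edges. Cluster origin is dated from the
#' anchoring paralog relations: `pre-WGD` when any anchor pair predates the
#' WGD, `post-WGD` when all anchor pairs postdate it, `mixed` otherwise
#' (including clusters whose edges are all same-gene anchored).
#'
#' @param hit_pairs output of [self_hits()].
#' @param associations classified associations ([associate_cnes()]).
#' @param orthology orthology table.
#' @param species species whose gene paralogy is consulted.
#' @return data frame: `cluster_id`, `members` (comma list), `n_members`,
#'   `anchor_orthogroups` (comma list), `origin`.
#' @export
paralogy_clusters <- function(hit_pairs, associations, orthology, species) {
  targets <- function(id) {
    g <- associations$target_genes[associations$cne_id == id]
    if (!length(g) || !nzchar(g)) character(0) else strsplit(g, ",")[[1]]
  }
  ogs_of <- function(id) {
    g <- associations$target_orthogroups[associations$cne_id == id]
    if (!length(g) || !nzchar(g)) character(0) else strsplit(g, ",")[[1]]
  }
  kept <- list()
  for (i in seq_len(nrow(hit_pairs))) {
    ta <- targets(hit_pairs$a[i]); tb <- targets(hit_pairs$b[i])
    if (!length(ta) || !length(tb)) {
      cne_log(sprintf("paralogy: dropped edge %s-%s (member without target)",
                      hit_pairs$a[i], hit_pairs$b[i]), level = "debug")
      next
    }
    origins <- character(0); ok <- FALSE
    for (g1 in ta) for (g2 in tb) {
      if (g1 == g2) { ok <- TRUE }
      else {
        o <- .pair_origin(orthology, species, g1, g2)
        if (!is.na(o) && o != "none") { ok <- TRUE; origins <- c(origins, o) }
      }
    }
    if (ok)
      kept[[length(kept) + 1L]] <- data.frame(
        a = hit_pairs$a[i], b = hit_pairs$b[i],
        origins = paste(unique(origins), collapse = ","),
        stringsAsFactors = FALSE)
  }
  if (!length(kept))
    return(data.frame(cluster_id = character(), members = character(),
                      n_members = integer(), anchor_orthogroups = character(),
                      origin = character(), stringsAsFactors = FALSE))
  edges <- do.call(rbind, kept)
  g <- igraph::graph_from_data_frame(edges[c("a", "b")], directed = FALSE)
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(ci) {
    members <- names(comp$membership)[comp$membership == ci]
    esel <- edges$a %in% members & edges$b %in% members
    origins <- unlist(strsplit(edges$origins[esel], ","))
    origins <- origins[nzchar(origins)]
    origin <- if (any(origins == "pre-WGD")) "pre-WGD"
    else if (length(origins) && all(origins == "post-WGD")) "post-WGD"
    else "mixed"
    ogs <- sort(unique(unlist(lapply(members, ogs_of))))
    data.frame(cluster_id = sprintf("cl%03d", ci),
               members = paste(sort(members), collapse = ","),
               n_members = length(members),
               anchor_orthogroups = paste(ogs, collapse = ","),
               origin = origin, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Common paralogy clusters between two reference groups
#'
#' Clusters from two groups (e.g. a teleost-analog and a vertebrate-analog
#' reference) are matched when their anchor orthogroup sets intersect;
#' one-to-many matches are reported once per pair.
#'
#' @param clusters_a,clusters_b outputs of [paralogy_clusters()].
#' @return data frame `cluster_a`, `cluster_b`, `shared_orthogroups`.
#' @export
common_clusters <- function(clusters_a, clusters_b) {
  out <- list()
  for (i in seq_len(nrow(clusters_a))) {
    oa <- strsplit(clusters_a$anchor_orthogroups[i], ",")[[1]]
    for (j in seq_len(nrow(clusters_b))) {
      ob <- strsplit(clusters_b$anchor_orthogroups[j], ",")[[1]]
      shared <- intersect(oa, ob)
      if (length(shared))
        out[[length(out) + 1L]] <- data.frame(
          cluster_a = clusters_a$cluster_id[i],
          cluster_b = clusters_b$cluster_id[j],
          shared_orthogroups = paste(sort(shared), collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cluster_a = character(), cluster_b = character(),
                      shared_orthogroups = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
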