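#' Parameters for cross-genome CNE search
#'
#' Word size 6 with best-hit semantics and an E-value ceiling of 1e-6. The
#' internal seeder requires two non-overlapping word hits on the same
#' diagonal within `two_hit_window` bp before extending (pure 6-mer seeding
#' is quadratic noise on random sequence; two-hit seeding preserves
#' sensitivity for the >= 100 bp, >= 70% identity targets of interest).
#' `single_hit = TRUE` switches to classic one-hit seeding.
#'
#' @param word_size exact word seed length (>= 4).
#' @param evalue_max E-value ceiling for reported hits.
#' @param max_target_seqs,max_hsps best-hit bookkeeping (kept at 1; hit
#'   counting for copy-number questions uses [count_hits()] which relaxes
#'   them).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @param x_drop ungapped x-drop threshold.
#' @param two_hit_window maximum diagonal distance between the two seeding
#'   word hits.
#' @param single_hit disable the two-hit requirement.
#' @return list of class `search_params`.
#' @export
search_params <- function(word_size = 6L, evalue_max = 1e-6,
                          max_target_seqs = 1L, max_hsps = 1L,
                          match = 1L, mismatch = -2L,
                          gap_open = -5L, gap_extend = -2L,
                          x_drop = 15L, two_hit_window = 40L,
                          single_hit = FALSE) {
  stopifnot(word_size >= 4, evalue_max > 0)
  structure(list(word_size = as.integer(word_size), evalue_max = evalue_max,
                 max_target_seqs = as.integer(max_target_seqs),
                 max_hsps = as.integer(max_hsps), match = as.integer(match),
                 mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), x_drop = as.integer(x_drop),
                 two_hit_window = as.integer(two_hit_window),
                 single_hit = isTRUE(single_hit)),
            class = "search_params")
}

.empty_hits <- function() {
  data.frame(query_id = character(), species_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), bitscore = numeric(),
             evalue = numeric(), identity = numeric(),
             q_cov_start = integer(), q_cov_end = integer(),
             stringsAsFactors = FALSE)
}

#' Search query sequences against one genome
#'
#' Exact word seeding on both strands, ungapped x-drop extension, and
#' Karlin-Altschul E-values `E = K * m * n * exp(-lambda * S)` with `m` the
#' query length and `n` the total ungapped genome length (summed over
#' sequences). All hits with `E <= evalue_max` are returned; use
#' [best_hits()] for best-hit-per-query semantics.
#'
#' @param queries named character vector of query sequences.
#' @param genome single-species entry of a [genome_set()] (or any list with
#'   a `sequences` element).
#' @param params a [search_params()].
#' @param species_id species label stamped on the hits.
#' @return hit data frame: genomic `chrom`/`start`/`end`/`strand`, raw and
#'   bit scores, E-value, identity, and the covered query range
#'   (`q_cov_start`, `q_cov_end`, forward query coordinates).
#' @export
search_genome <- function(queries, genome, params = search_params(),
                          species_id = NA_character_) {
  stopifnot(length(queries) > 0, !is.null(names(queries)))
  if (any(nchar(queries) < params$word_size))
    stop("query shorter than word_size")
  ka <- karlin_altschul_params(params$match, params$mismatch)
  n_total <- sum(nchar(genome$sequences))
  # permissive raw-score floor from the shortest query; exact E filter below
  m_min <- min(nchar(queries))
  min_score <- max(1L, floor(log(ka$K * m_min * n_total / params$evalue_max) /
                               ka$lambda))
  qfwd <- unname(queries)
  qrev <- revcomp(qfwd)
  out <- list()
  for (chr in names(genome$sequences)) {
    for (strand in c("+", "-")) {
      qscan <- if (strand == "+") qfwd else qrev
      hits <- cpp_seed_extend_multi(genome$sequences[[chr]], qscan,
                                    params$word_size, params$match,
                                    params$mismatch, params$x_drop,
                                    min_score, !params$single_hit,
                                    params$two_hit_window)
      if (nrow(hits) == 0) next
      qlen <- nchar(qfwd)[hits$query]
      if (strand == "+") {
        qs <- hits$qstart; qe <- hits$qend
      } else {
        qs <- qlen - hits$qend; qe <- qlen - hits$qstart
      }
      out[[length(out) + 1L]] <- data.frame(
        query_id = names(queries)[hits$query], species_id = species_id,
        chrom = chr, start = hits$sstart, end = hits$send, strand = strand,
        score = as.numeric(hits$score),
        bitscore = bitscore(hits$score, ka),
        evalue = evalue(hits$score, qlen, n_total, ka),
        identity = hits$matches / (hits$send - hits$sstart),
        q_cov_start = qs, q_cov_end = qe, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_hits())
  res <- do.call(rbind, out)
  res <- res[res$evalue <= params$evalue_max, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Best hit per query
#'
#' Ties break by lowest E-value, then highest score, then lexicographic
#' (chrom, start).
#'
#' @param hits output of [search_genome()].
#' @return hit data frame with at most one row per `query_id`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query_id, hits$evalue, -hits$score, hits$chrom, hits$start)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count hits of each query in a genome
#'
#' Relaxes best-hit bookkeeping to answer copy-number questions (the repeat
#' `cutoffs` filter, single-copy marker selection). Hits overlapping on the
#' same genomic position and strand are merged before counting.
#'
#' @inheritParams search_genome
#' @return named integer vector of hit counts along `names(queries)`.
#' @export
count_hits <- function(queries, genome, params = search_params(),
                       species_id = NA_character_) {
  hits <- search_genome(queries, genome, params, species_id)
  counts <- setNames(integer(length(queries)), names(queries))
  if (nrow(hits) == 0) return(counts)
  for (qid in unique(hits$query_id)) {
    h <- hits[hits$query_id == qid, , drop = FALSE]
    k <- 0L
    for (key in unique(paste(h$chrom, h$strand))) {
      hh <- h[paste(h$chrom, h$strand) == key, , drop = FALSE]
      k <- k + length(IRanges::reduce(IRanges::IRanges(hh$start + 1L, hh$end)))
    }
    counts[qid] <- k
  }
  counts
}

#' Presence/absence matrix of CNEs across genomes
#'
#' Every CNE is searched against every genome; each (CNE, species) cell holds
#' the best hit or is absent. The reference species of a CNE is filled from
#' the CNE's own coordinates without search (identity 1, E-value 0).
#'
#' @param cne_sets list of CNE set data frames (see [detect_cnes()]), each
#'   with a `ref_species` column naming a genome in `genomes`.
#' @param genomes a [genome_set()].
#' @param params a [search_params()].
#' @return long-format data frame of class `presence_matrix` (one row per
#'   present cell).
#' @export
build_presence_matrix <- function(cne_sets, genomes, params = search_params()) {
  if (is.data.frame(cne_sets)) cne_sets <- list(cne_sets)
  rows <- list()
  for (cs in cne_sets) {
    if (nrow(cs) == 0) next
    ref <- unique(cs$ref_species)
    stopifnot(length(ref) == 1)
    if (!ref %in% names(genomes))
      stop("missing genome for reference species ", ref)
    seqs <- setNames(vapply(seq_len(nrow(cs)), function(i)
      genome_subseq(genomes, ref, cs$chrom[i], cs$start[i], cs$end[i]),
      character(1)), cs$id)
    for (sp in names(genomes)) {
      if (sp == ref) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = cs$id, species_id = sp, chrom = cs$chrom,
          start = cs$start, end = cs$end, strand = cs$strand,
          score = NA_real_, bitscore = NA_real_, evalue = 0,
          identity = 1, q_cov_start = 0L, q_cov_end = cs$end - cs$start,
          stringsAsFactors = FALSE)
      } else {
        if (is.null(genomes[[sp]]))
          stop("missing genome for species ", sp)
        rows[[length(rows) + 1L]] <-
          best_hits(search_genome(seqs, genomes[[sp]], params, sp))
      }
    }
  }
  pm <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
  rownames(pm) <- NULL
  class(pm) <- c("presence_matrix", class(pm))
  pm
}

#' Species in which a CNE is present
#' @param pm a presence matrix.
#' @param cne_id CNE id.
#' @return character vector of species ids.
#' @export
presence_species <- function(pm, cne_id) {
  unique(pm$species_id[pm$query_id == cne_id])
}

#' Write a presence matrix as a wide TSV
#'
#' One row per CNE; per-species columns formatted
#' `chrom:start-end:strand:identity:evalue`, `.` for absence.
#'
#' @param pm a presence matrix.
#' @param path output file.
#' @param species column order; defaults to the species present.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pm, path, species = NULL) {
  species <- species %||% sort(unique(pm$species_id))
  ids <- unique(pm$query_id)
  wide <- data.frame(cne_id = ids, stringsAsFactors = FALSE)
  for (sp in species) {
    sub <- pm[pm$species_id == sp, , drop = FALSE]
    cell <- setNames(sprintf("%s:%d-%d:%s:%.4f:%.3g", sub$chrom, sub$start,
                             sub$end, sub$strand, sub$identity, sub$evalue),
                     sub$query_id)
    wide[[sp]] <- unname(cell[ids])
    wide[[sp]][is.na(wide[[sp]])] <- "."
  }
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
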