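#' Parameters for sliding-window CNE detection
#'
#' Defaults follow the standard teleost CNE screen: 100 bp windows at >= 70%
#' identity, elements of at least 100 bp, and removal of elements seen more
#' than 4 times in either genome of the focal pair (`max_hits`, the
#' "cutoffs" repeat filter; exactly `max_hits` hits survives).
#'
#' @param window window size in alignment columns.
#' @param min_identity minimum fraction of matching columns per window.
#' @param max_hits maximum allowed hit count per element (inclusive).
#' @param min_length minimum element length (bp, >= window).
#' @return list of class `detect_params`.
#' @export
detect_params <- function(window = 100L, min_identity = 0.70,
                          max_hits = 4L, min_length = 100L) {
  stopifnot(window >= 1, min_identity > 0, min_identity <= 1,
            min_length >= window, max_hits >= 1)
  structure(list(window = as.integer(window), min_identity = min_identity,
                 max_hits = as.integer(max_hits),
                 min_length = as.integer(min_length)),
            class = "detect_params")
}

# per-column status of a block: 1 match, 0 mismatch/gap, -1 excluded
block_status <- function(b, excluded_ref = NULL) {
  r <- strsplit(toupper(b$ref_aln), "")[[1]]
  q <- strsplit(toupper(b$query_aln), "")[[1]]
  st <- as.integer(r == q & r != "-" & r %in% c("A", "C", "G", "T"))
  if (!is.null(excluded_ref) && length(excluded_ref)) {
    rpos <- b$ref_start + cumsum(r != "-") - (r != "-")
    st[(r != "-") & (rpos %in% excluded_ref)] <- -1L
  }
  st
}

#' Flag alignment columns overlapping exons or repeats
#'
#' Columns whose reference base lies inside an exon or repeat interval are
#' excluded from window scanning; gap columns (no reference base) are never
#' excluded by annotation. Blocks that are fully excluded are dropped.
#'
#' @param blocks alignment block data frame.
#' @param exons,repeats reference-species interval data frames.
#' @return `blocks` with a list-column `excluded` of excluded reference
#'   positions per block.
#' @export
mask_annotations <- function(blocks, exons = NULL, repeats = NULL) {
  ann <- rbind(
    if (!is.null(exons) && nrow(exons)) exons[c("chrom", "start", "end")],
    if (!is.null(repeats) && nrow(repeats)) repeats[c("chrom", "start", "end")])
  excl <- vector("list", nrow(blocks))
  keep <- rep(TRUE, nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (is.null(ann) || nrow(ann) == 0) { excl[[i]] <- integer(0); next }
    a <- ann[ann$chrom == b$ref_chrom & ann$start < b$ref_end &
               ann$end > b$ref_start, , drop = FALSE]
    if (nrow(a) == 0) { excl[[i]] <- integer(0); next }
    pos <- unique(unlist(lapply(seq_len(nrow(a)), function(j)
      seq(max(a$start[j], b$ref_start), min(a$end[j], b$ref_end) - 1L))))
    excl[[i]] <- as.integer(pos)
    if (length(pos) >= b$ref_end - b$ref_start) keep[i] <- FALSE
  }
  blocks$excluded <- excl
  blocks[keep, , drop = FALSE]
}

#' Sliding-window scan of one block for conserved stretches
#'
#' Slides a window of `params$window` alignment columns one column at a time
#' over excluded-free stretches; window identity counts gap columns as
#' mismatches; windows with identity >= `min_identity` mark all their
#' columns. Marked columns are projected to reference coordinates.
#'
#' @param b one-row block data frame (with optional `excluded` list-column).
#' @param params a [detect_params()].
#' @return integer vector of marked reference positions (0-based).
#' @export
scan_conserved <- function(b, params = detect_params()) {
  st <- block_status(b, if (!is.null(b$excluded)) b$excluded[[1]])
  if (length(st) < params$window) return(integer(0))
  min_matches <- as.integer(ceiling(params$window * params$min_identity - 1e-9))
  marked <- cpp_window_scan(st, params$window, min_matches)
  r <- strsplit(b$ref_aln, "")[[1]]
  rpos <- b$ref_start + cumsum(r != "-") - (r != "-")
  sort(unique(rpos[marked & r != "-"]))
}

#' Merge marked positions into candidate elements
#'
#' Maximal runs of consecutive marked reference positions become elements.
#' Because a qualifying window may straddle an element's true edge, run ends
#' can carry unsupported flanking bases; each run is therefore refined to
#' its maximal-scoring subsegment under break-even scoring at the identity
#' threshold (match `1 - min_identity`, mismatch `-min_identity`), which
#' trims exactly the terminal stretches whose local identity falls below
#' `min_identity`. Refined elements shorter than `min_length` are
#' discarded; mean identity is recomputed per element over its own columns.
#'
#' @param marked integer vector of marked reference positions from one block.
#' @param b the block the positions came from.
#' @param params a [detect_params()].
#' @param refine_boundaries disable to keep full marked runs.
#' @return data frame of elements (`chrom`, `start`, `end`, `mean_identity`).
#' @export
merge_candidates <- function(marked, b, params = detect_params(),
                             refine_boundaries = TRUE) {
  if (!length(marked)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_identity = numeric(), stringsAsFactors = FALSE))
  }
  marked <- sort(marked)
  run_id <- cumsum(c(1L, diff(marked) != 1L))
  st <- block_status(b)
  r <- strsplit(b$ref_aln, "")[[1]]
  rpos <- b$ref_start + cumsum(r != "-") - (r != "-")
  out <- lapply(split(marked, run_id), function(run) {
    lo <- run[1]; hi <- run[length(run)] + 1L
    if (refine_boundaries) {
      # per-position match indicator over the run, in reference coordinates
      pos_match <- st == 1L & (strsplit(b$ref_aln, "")[[1]] != "-") &
        rpos >= lo & rpos < hi
      m <- rep(FALSE, hi - lo)
      m[rpos[pos_match] - lo + 1L] <- TRUE
      seg <- .max_scoring_segment(ifelse(m, 1 - params$min_identity,
                                         -params$min_identity))
      if (is.null(seg)) return(NULL)
      lo2 <- lo + seg[1] - 1L; hi2 <- lo + seg[2]
      lo <- lo2; hi <- hi2
    }
    if (hi - lo < params$min_length) return(NULL)
    cols <- rpos >= lo & rpos < hi
    data.frame(chrom = b$ref_chrom, start = lo, end = hi,
               mean_identity = mean(st[cols] == 1L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_identity = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Kadane maximum-sum contiguous segment; returns c(start, end) 1-based
# inclusive indices or NULL when all-negative
.max_scoring_segment <- function(x) {
  best <- -Inf; cur <- 0; cur_start <- 1L
  bs <- be <- 0L
  for (i in seq_along(x)) {
    if (cur <= 0) { cur <- x[i]; cur_start <- i }
    else cur <- cur + x[i]
    if (cur > best) { best <- cur; bs <- cur_start; be <- i }
  }
  if (best <= 0) return(NULL)
  c(bs, be)
}

#' Remove repetitive elements by copy number
#'
#' Each element's sequence is searched against both genomes of the focal
#' pair; elements with more than `max_hits` hits in either genome are
#' removed (exactly `max_hits` survives).
#'
#' @param elements element data frame with `chrom`, `start`, `end`.
#' @param ref_genome,query_genome [genome_set()] entries of the focal pair.
#' @param s_params a [search_params()].
#' @param max_hits inclusive hit-count ceiling.
#' @return filtered `elements`, with `n_hits_ref`/`n_hits_query` columns.
#' @export
filter_repetitive <- function(elements, ref_genome, query_genome,
                              s_params = search_params(), max_hits = 4L) {
  if (nrow(elements) == 0) return(elements)
  seqs <- setNames(vapply(seq_len(nrow(elements)), function(i)
    substr(ref_genome$sequences[[elements$chrom[i]]],
           elements$start[i] + 1L, elements$end[i]), character(1)),
    sprintf("el%05d", seq_len(nrow(elements))))
  elements$n_hits_ref <- unname(count_hits(seqs, ref_genome, s_params))
  elements$n_hits_query <- unname(count_hits(seqs, query_genome, s_params))
  keep <- elements$n_hits_ref <= max_hits & elements$n_hits_query <= max_hits
  cne_log(sprintf("filter_repetitive: removed %d of %d element(s)",
                  sum(!keep), nrow(elements)))
  out <- elements[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' De novo CNE detection from a focal species pair
#'
#' Full detection stage: two-round alignment, chaining, netting,
#' exon/repeat masking, window scan, merging and the repeat copy-number
#' filter. Elements are reported on the reference species.
#'
#' @param genomes a [genome_set()].
#' @param ref_species,query_species focal pair; elements are anchored on
#'   `ref_species`.
#' @param params a [detect_params()].
#' @param aln_params an [aligner_params()].
#' @param s_params a [search_params()] for the copy-number filter.
#' @param id_prefix prefix for element ids.
#' @param net optional precomputed netted blocks (skips alignment).
#' @return CNE set data frame: `id`, `ref_species`, `chrom`, `start`, `end`,
#'   `strand`, `length`, `mean_identity`, `source_pair`.
#' @export
detect_cnes <- function(genomes, ref_species, query_species,
                        params = detect_params(),
                        aln_params = aligner_params(),
                        s_params = search_params(),
                        id_prefix = NULL, net = NULL) {
  ref <- genomes[[ref_species]]
  qry <- genomes[[query_species]]
  if (is.null(net)) {
    blocks <- two_round_align(ref, qry, aln_params)
    blocks <- chain_blocks(blocks)
    net <- net_chains(blocks, aln_params)
  }
  net <- mask_annotations(net, ref$exons, ref$repeats)
  cand <- list()
  for (i in seq_len(nrow(net))) {
    b <- net[i, , drop = FALSE]
    cand[[length(cand) + 1L]] <- merge_candidates(scan_conserved(b, params), b, params)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) {
    out <- data.frame(id = character(), ref_species = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      mean_identity = numeric(), source_pair = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  cand <- cand[cand$end - cand$start >= params$min_length, , drop = FALSE]
  cand <- filter_repetitive(cand, ref, qry, s_params, params$max_hits)
  cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
  prefix <- id_prefix %||% paste0(substr(ref_species, 1, 1), "CNE")
  out <- data.frame(id = sprintf("%s_%05d", prefix, seq_len(nrow(cand))),
                    ref_species = ref_species, chrom = cand$chrom,
                    start = cand$start, end = cand$end, strand = "+",
                    length = cand$end - cand$start,
                    mean_identity = cand$mean_identity,
                    source_pair = paste(ref_species, query_species, sep = ":"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract the sequences of a CNE set
#' @param cnes CNE set data frame.
#' @param genomes a [genome_set()].
#' @return named character vector keyed by CNE id.
#' @export
cne_sequences <- function(cnes, genomes) {
  setNames(vapply(seq_len(nrow(cnes)), function(i)
    genome_subseq(genomes, cnes$ref_species[i], cnes$chrom[i],
                  cnes$start[i], cnes$end[i], cnes$strand[i]), character(1)),
    cnes$id)
}
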