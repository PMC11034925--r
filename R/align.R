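#' Parameters for the internal seed-and-extend aligner
#'
#' The built-in aligner finds exact seed matches on both strands and extends
#' them without gaps under an x-drop rule; blocks are trimmed back to their
#' maximum-scoring extent and dropped below `min_block_score`. It targets
#' substitution-only simulated cohorts; alignments of real genomes are
#' expected to be imported from external aligners via [read_axt()], in which
#' case `external_params` records the external parameterisation verbatim
#' (e.g. LASTZ-style `M`, `E`, `H` settings).
#'
#' @param seed_length exact-match seed length (>= 4).
#' @param match,mismatch,gap_open,gap_extend scores; penalties negative.
#' @param x_drop ungapped x-drop threshold.
#' @param min_block_score minimum block score kept.
#' @param external_params opaque key-value list, passed through untouched.
#' @return list of class `aligner_params`.
#' @export
aligner_params <- function(seed_length = 12L, match = 1L, mismatch = -2L,
                           gap_open = -5L, gap_extend = -2L,
                           x_drop = 15L, min_block_score = 30L,
                           external_params = list()) {
  stopifnot(seed_length >= 4, match > 0, mismatch < 0,
            gap_open < 0, gap_extend < 0, x_drop > 0)
  structure(list(seed_length = as.integer(seed_length), match = as.integer(match),
                 mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), x_drop = as.integer(x_drop),
                 min_block_score = as.integer(min_block_score),
                 external_params = external_params),
            class = "aligner_params")
}

.empty_blocks <- function() {
  data.frame(ref_chrom = character(), ref_start = integer(), ref_end = integer(),
             query_chrom = character(), query_start = integer(),
             query_end = integer(), strand = character(), score = numeric(),
             ref_aln = character(), query_aln = character(),
             stringsAsFactors = FALSE)
}

#' Pairwise alignment of two genomes by seed-and-extend
#'
#' Every (reference sequence, query sequence, strand) combination is scanned
#' for exact `seed_length`-mers (seeds containing `N` are never formed) and
#' seeds are extended without gaps under the x-drop rule. Coordinates are
#' 0-based half-open; minus-strand query intervals are reported on the
#' forward strand, with `query_aln` stored in reference orientation.
#'
#' @param ref_genome,query_genome single-species entries of a [genome_set()]
#'   (lists with a `sequences` element).
#' @param params an [aligner_params()] object.
#' @return data frame of alignment blocks sorted by reference position.
#' @export
seed_extend_align <- function(ref_genome, query_genome, params = aligner_params()) {
  rseqs <- ref_genome$sequences
  qseqs <- query_genome$sequences
  stopifnot(length(rseqs) > 0, length(qseqs) > 0)
  out <- list()
  for (rc in names(rseqs)) {
    for (strand in c("+", "-")) {
      qnames <- names(qseqs)
      qscan <- if (strand == "+") unname(qseqs) else revcomp(unname(qseqs))
      hits <- cpp_seed_extend_multi(rseqs[[rc]], qscan,
                                    params$seed_length, params$match,
                                    params$mismatch, params$x_drop,
                                    params$min_block_score,
                                    FALSE, 0L)
      if (nrow(hits) == 0) next
      qc <- qnames[hits$query]
      qlen <- nchar(qseqs)[hits$query]
      if (strand == "+") {
        qs <- hits$qstart; qe <- hits$qend
      } else {
        qs <- qlen - hits$qend; qe <- qlen - hits$qstart
      }
      qaln <- substring(qscan[hits$query], hits$qstart + 1L, hits$qend)
      out[[length(out) + 1L]] <- data.frame(
        ref_chrom = rc, ref_start = hits$sstart, ref_end = hits$send,
        query_chrom = qc, query_start = qs, query_end = qe,
        strand = strand, score = as.numeric(hits$score),
        ref_aln = substring(rseqs[[rc]], hits$sstart + 1L, hits$send),
        query_aln = qaln, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_blocks())
  blocks <- do.call(rbind, out)
  blocks <- blocks[order(blocks$ref_chrom, blocks$ref_start, blocks$query_chrom,
                         blocks$query_start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Two-round alignment with intermediate masking
#'
#' Runs the aligner, masks every reference and query position covered by a
#' round-1 block with `N`, aligns again, and returns the union with a
#' `round` label. Round-2 blocks are trimmed so that they never overlap
#' round-1 blocks on the reference.
#'
#' @inheritParams seed_extend_align
#' @return block data frame with a `round` column.
#' @export
two_round_align <- function(ref_genome, query_genome, params = aligner_params()) {
  r1 <- seed_extend_align(ref_genome, query_genome, params)
  r1$round <- if (nrow(r1)) 1L else integer(0)
  if (nrow(r1) == 0) return(r1)
  mask_seqs <- function(seqs, ints) {
    for (chr in unique(ints$chrom)) {
      chars <- strsplit(seqs[[chr]], "")[[1]]
      sel <- ints[ints$chrom == chr, , drop = FALSE]
      pos <- unlist(lapply(seq_len(nrow(sel)), function(i)
        (sel$start[i] + 1L):sel$end[i]))
      chars[unique(pos)] <- "N"
      seqs[[chr]] <- paste(chars, collapse = "")
    }
    seqs
  }
  ref_cov <- data.frame(chrom = r1$ref_chrom, start = r1$ref_start,
                        end = r1$ref_end, stringsAsFactors = FALSE)
  query_cov <- data.frame(chrom = r1$query_chrom, start = r1$query_start,
                          end = r1$query_end, stringsAsFactors = FALSE)
  ref2 <- list(sequences = mask_seqs(ref_genome$sequences, ref_cov))
  query2 <- list(sequences = mask_seqs(query_genome$sequences, query_cov))
  r2 <- seed_extend_align(ref2, query2, params)
  if (nrow(r2)) {
    r2 <- trim_blocks_against(r2, ref_cov, params)
    r2 <- r2[r2$score >= params$min_block_score, , drop = FALSE]
  }
  r2$round <- if (nrow(r2)) 2L else integer(0)
  out <- rbind(r1, r2)
  out <- out[order(out$ref_chrom, out$ref_start, out$query_chrom,
                   out$query_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# number of reference bases in each alignment column of a gapped row
.ref_col_pos <- function(ref_aln) {
  cols <- strsplit(ref_aln, "")[[1]]
  cumsum(cols != "-") - (cols != "-")  # 0-based ref offset of each column
}

#' Trim an alignment block to a reference sub-interval
#'
#' Keeps alignment columns whose reference position lies in
#' `[lo, hi)` (0-based, relative to the chromosome). Handles gapped blocks
#' by walking columns; the score is recomputed from the retained columns.
#'
#' @param b one-row block data frame.
#' @param lo,hi reference coordinate range to keep.
#' @param params [aligner_params()] used to rescore.
#' @return one-row block data frame, or `NULL` if nothing remains.
#' @export
trim_block_ref_range <- function(b, lo, hi, params = aligner_params()) {
  lo <- max(lo, b$ref_start); hi <- min(hi, b$ref_end)
  if (hi <= lo) return(NULL)
  if (lo == b$ref_start && hi == b$ref_end) return(b)
  rcols <- strsplit(b$ref_aln, "")[[1]]
  qcols <- strsplit(b$query_aln, "")[[1]]
  rpos <- b$ref_start + cumsum(rcols != "-") - (rcols != "-")
  keep <- rpos >= lo & rpos < hi & rcols != "-"
  # expand to include columns between first and last kept (internal q-gaps)
  rng <- range(which(keep))
  keep_cols <- seq(rng[1], rng[2])
  rsub <- rcols[keep_cols]; qsub <- qcols[keep_cols]
  qoff_all <- cumsum(qcols != "-") - (qcols != "-")
  q_kept <- qoff_all[keep_cols][qsub != "-"]
  if (!length(q_kept)) return(NULL)
  if (b$strand == "+") {
    qs <- b$query_start + min(q_kept); qe <- b$query_start + max(q_kept) + 1L
  } else {
    # query_aln is in reference orientation: alignment query-offset o maps to
    # genomic position query_end - 1 - o
    qs <- b$query_end - max(q_kept) - 1L
    qe <- b$query_end - min(q_kept)
  }
  b2 <- b
  b2$ref_start <- lo; b2$ref_end <- hi
  b2$query_start <- qs; b2$query_end <- qe
  b2$ref_aln <- paste(rsub, collapse = "")
  b2$query_aln <- paste(qsub, collapse = "")
  b2$score <- score_block(b2, params)
  b2
}

#' Score a block from its alignment strings
#'
#' Matches and mismatches use the aligner's match/mismatch scores; each gap
#' run costs `gap_open` plus `gap_extend` per gap column.
#'
#' @param b one-row block data frame.
#' @param params [aligner_params()].
#' @return numeric score.
#' @export
score_block <- function(b, params = aligner_params()) {
  r <- strsplit(toupper(b$ref_aln), "")[[1]]
  q <- strsplit(toupper(b$query_aln), "")[[1]]
  gap <- r == "-" | q == "-"
  m <- !gap & r == q & r %in% c("A", "C", "G", "T")
  runs <- rle(gap)
  n_open <- sum(runs$values)  # number of gap runs
  sum(m) * params$match + sum(!gap & !m) * params$mismatch +
    n_open * params$gap_open + sum(gap) * params$gap_extend
}

#' Fraction of matching columns in each block
#' @param blocks block data frame.
#' @return numeric vector of identities in `[0, 1]`.
#' @export
block_identity <- function(blocks) {
  vapply(seq_len(nrow(blocks)), function(i) {
    r <- strsplit(toupper(blocks$ref_aln[i]), "")[[1]]
    q <- strsplit(toupper(blocks$query_aln[i]), "")[[1]]
    mean(r == q & r != "-" & r %in% c("A", "C", "G", "T"))
  }, numeric(1))
}

# trim blocks so that they avoid a set of reference intervals
trim_blocks_against <- function(blocks, cover, params) {
  out <- list()
  cov_by_chr <- split(cover, cover$chrom)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, , drop = FALSE]
    cc <- cov_by_chr[[b$ref_chrom]]
    if (is.null(cc)) { out[[length(out) + 1L]] <- b; next }
    covered <- IRanges::reduce(IRanges::IRanges(cc$start + 1L, cc$end))
    free <- IRanges::setdiff(IRanges::IRanges(b$ref_start + 1L, b$ref_end), covered)
    for (j in seq_along(free)) {
      piece <- trim_block_ref_range(b, IRanges::start(free)[j] - 1L,
                                    IRanges::end(free)[j], params)
      if (!is.null(piece)) out[[length(out) + 1L]] <- piece
    }
  }
  if (!length(out)) return(.empty_blocks())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
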