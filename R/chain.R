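#' Collinear chaining of alignment blocks
#'
#' Within each (reference sequence, query sequence, strand) group, blocks are
#' joined into maximum-score collinear chains by dynamic programming. A link
#' between consecutive blocks is allowed when the block strictly follows on
#' both genomes and both gaps are at most `max_gap`; it costs
#' `gap_open + per_bp_gap_cost * (ref_gap + query_gap)`. The best-scoring
#' chain is extracted, removed, and the programme repeated, so every block
#' belongs to exactly one chain. Blocks that overlap on the reference are
#' never linked and therefore end up in different chains (ref overlap is
#' legitimate between paralogous chains and is resolved later by
#' [net_chains()]).
#'
#' @param blocks alignment block data frame.
#' @param gap_open_cost flat cost per link.
#' @param per_bp_gap_cost cost per gap base (both sides summed).
#' @param max_gap maximum allowed gap on either side.
#' @return `blocks` with `chain_id` (globally unique) and chain-local order;
#'   chain summaries are available via [chain_summary()].
#' @export
chain_blocks <- function(blocks, gap_open_cost = 50, per_bp_gap_cost = 0.5,
                         max_gap = 10000) {
  if (nrow(blocks) == 0) {
    blocks$chain_id <- integer(0)
    return(blocks)
  }
  grp <- paste(blocks$ref_chrom, blocks$query_chrom, blocks$strand, sep = "\r")
  blocks <- blocks[order(grp, blocks$ref_start, blocks$query_start), , drop = FALSE]
  grp <- paste(blocks$ref_chrom, blocks$query_chrom, blocks$strand, sep = "\r")
  next_id <- 0L
  blocks$chain_id <- NA_integer_
  for (g in unique(grp)) {
    idx <- which(grp == g)
    # on the minus strand collinearity runs ref-forward / query-backward in
    # forward coordinates; mirror the query axis so the DP sees both increasing
    minus <- blocks$strand[idx[1]] == "-"
    qs <- if (minus) -blocks$query_end[idx] else blocks$query_start[idx]
    qe <- if (minus) -blocks$query_start[idx] else blocks$query_end[idx]
    cid <- cpp_chain_blocks(blocks$ref_start[idx], blocks$ref_end[idx],
                            qs, qe, blocks$score[idx],
                            gap_open_cost, per_bp_gap_cost, max_gap)
    blocks$chain_id[idx] <- cid + next_id
    next_id <- next_id + max(cid)
  }
  rownames(blocks) <- NULL
  attr(blocks, "chain_costs") <- list(gap_open_cost = gap_open_cost,
                                      per_bp_gap_cost = per_bp_gap_cost,
                                      max_gap = max_gap)
  blocks
}

#' Per-chain summary (span, total score)
#'
#' The total score is the sum of block scores minus link costs, i.e. the
#' chaining DP objective.
#'
#' @param blocks output of [chain_blocks()].
#' @return data frame with one row per chain, sorted by total score.
#' @export
chain_summary <- function(blocks) {
  costs <- attr(blocks, "chain_costs") %||%
    list(gap_open_cost = 50, per_bp_gap_cost = 0.5, max_gap = 10000)
  o <- order(blocks$chain_id, blocks$ref_start)
  cid <- blocks$chain_id[o]
  groups <- split(seq_along(cid), cid)
  score_of <- function(idx) {
    link <- 0
    if (length(idx) > 1) {
      i <- o[idx]
      rgap <- blocks$ref_start[i][-1] - blocks$ref_end[i][-length(i)]
      qgap <- if (blocks$strand[i[1]] == "+")
        blocks$query_start[i][-1] - blocks$query_end[i][-length(i)]
      else blocks$query_start[i][-length(i)] - blocks$query_end[i][-1]
      link <- sum(costs$gap_open_cost + costs$per_bp_gap_cost * (rgap + qgap))
    }
    sum(blocks$score[o[idx]]) - link
  }
  first <- vapply(groups, function(idx) o[idx[1]], integer(1))
  out <- data.frame(
    chain_id = blocks$chain_id[first],
    n_blocks = lengths(groups),
    ref_chrom = blocks$ref_chrom[first],
    ref_start = vapply(groups, function(idx) min(blocks$ref_start[o[idx]]), numeric(1)),
    ref_end = vapply(groups, function(idx) max(blocks$ref_end[o[idx]]), numeric(1)),
    query_chrom = blocks$query_chrom[first],
    query_start = vapply(groups, function(idx) min(blocks$query_start[o[idx]]), numeric(1)),
    query_end = vapply(groups, function(idx) max(blocks$query_end[o[idx]]), numeric(1)),
    strand = blocks$strand[first],
    total_score = vapply(groups, score_of, numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$total_score, out$ref_start, out$query_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference-side netting of chains
#'
#' Chains are considered in order of decreasing total score; each is kept
#' only on reference intervals not already covered by a previously kept
#' chain, trimming blocks at base granularity where needed. The result has
#' zero reference overlap. Ties in score break by lower reference start,
#' then lower query start.
#'
#' @param blocks output of [chain_blocks()].
#' @param params [aligner_params()] used when rescoring trimmed blocks.
#' @return netted block data frame (columns as input).
#' @export
net_chains <- function(blocks, params = aligner_params()) {
  if (nrow(blocks) == 0) return(blocks)
  chains <- chain_summary(blocks)
  # per-chromosome coverage as plain logical vectors (cheap to query/update)
  covered <- new.env(parent = emptyenv())
  chrom_len <- tapply(blocks$ref_end, blocks$ref_chrom, max)
  for (chr in names(chrom_len))
    assign(chr, logical(chrom_len[[chr]]), envir = covered)
  kept <- list()
  blocks_by_chain <- split(seq_len(nrow(blocks)), blocks$chain_id)
  for (i in seq_len(nrow(chains))) {
    cov <- get(chains$ref_chrom[i], envir = covered)
    b <- blocks[blocks_by_chain[[as.character(chains$chain_id[i])]], , drop = FALSE]
    pieces <- list()
    for (j in seq_len(nrow(b))) {
      span <- (b$ref_start[j] + 1L):b$ref_end[j]
      taken <- cov[span]
      if (!any(taken)) {
        pieces[[length(pieces) + 1L]] <- b[j, , drop = FALSE]
        cov[span] <- TRUE
        next
      }
      if (all(taken)) next
      runs <- rle(!taken)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values)) {
        lo <- b$ref_start[j] + starts[k] - 1L
        hi <- b$ref_start[j] + ends[k]
        piece <- trim_block_ref_range(b[j, , drop = FALSE], lo, hi, params)
        if (!is.null(piece)) {
          pieces[[length(pieces) + 1L]] <- piece
          cov[(piece$ref_start + 1L):piece$ref_end] <- TRUE
        }
      }
    }
    if (!length(pieces)) next
    assign(chains$ref_chrom[i], cov, envir = covered)
    kept[[length(kept) + 1L]] <- do.call(rbind, pieces)
  }
  if (!length(kept)) return(.empty_blocks())
  net <- do.call(rbind, kept)
  net <- net[order(net$ref_chrom, net$ref_start), , drop = FALSE]
  rownames(net) <- NULL
  # invariant: overlap-free reference coverage
  for (chr in unique(net$ref_chrom)) {
    ir <- IRanges::IRanges(net$ref_start[net$ref_chrom == chr] + 1L,
                           net$ref_end[net$ref_chrom == chr])
    if (sum(IRanges::width(ir)) != sum(IRanges::width(IRanges::reduce(ir))))
      stop("internal error: net reference coverage overlaps")
  }
  net
}
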