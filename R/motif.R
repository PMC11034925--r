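#' Scan CNE sequences for a consensus motif
#'
#' Exact IUPAC-expanded matching on both strands. Palindromic motifs (their
#' own reverse complement, like TAATTA) occupy identical positions on both
#' strands and are counted once.
#'
#' @param seqs named character vector of element sequences (e.g. from
#'   [cne_sequences()]).
#' @param motif IUPAC consensus string (default `"TAATTA"`).
#' @return list with `occurrences` (data frame `cne_id`, `motif`, `offset`
#'   0-based, `strand`, `relative_position` = occurrence midpoint / element
#'   length) and `fraction_with_motif`.
#' @export
scan_consensus <- function(seqs, motif = "TAATTA") {
  stopifnot(length(seqs) > 0, nchar(motif) >= 1)
  ml <- nchar(motif)
  usable <- nchar(seqs) >= ml
  dss <- Biostrings::DNAStringSet(seqs[usable])
  pat <- Biostrings::DNAString(motif)
  rc <- Biostrings::reverseComplement(pat)
  palindrome <- as.character(rc) == toupper(motif)
  grab <- function(pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, dss, fixed = FALSE)
    starts <- Biostrings::startIndex(m)
    out <- list()
    for (i in seq_along(starts)) {
      if (is.null(starts[[i]]) || !length(starts[[i]])) next
      off <- starts[[i]] - 1L
      out[[length(out) + 1L]] <- data.frame(
        cne_id = names(dss)[i], motif = toupper(motif), offset = off,
        strand = strand,
        relative_position = (off + ml / 2) / nchar(seqs[[names(dss)[i]]]),
        stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  occ <- grab(pat, "+")
  if (!palindrome) occ <- rbind(occ, grab(rc, "-"))
  if (is.null(occ))
    occ <- data.frame(cne_id = character(), motif = character(),
                      offset = integer(), strand = character(),
                      relative_position = numeric(), stringsAsFactors = FALSE)
  occ <- occ[order(occ$cne_id, occ$offset), , drop = FALSE]
  rownames(occ) <- NULL
  list(occurrences = occ,
       fraction_with_motif = length(unique(occ$cne_id)) / length(seqs))
}

#' Positional distribution and central fraction of motif occurrences
#'
#' Histogram of relative positions (normalised to sum to 1) and the central
#' fraction: occurrences whose relative position falls in the middle tercile
#' `[1/3, 2/3)`.
#'
#' @param occurrences occurrence data frame from [scan_consensus()].
#' @param n_bins number of histogram bins over `[0, 1]`.
#' @return list with `histogram` (data frame `bin_start`, `bin_end`,
#'   `density`) and `central_fraction` (`NA` for empty input).
#' @export
positional_distribution <- function(occurrences, n_bins = 20L) {
  if (nrow(occurrences) == 0) {
    return(list(histogram = data.frame(bin_start = numeric(),
                                       bin_end = numeric(),
                                       density = numeric()),
                central_fraction = NA_real_))
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(occurrences$relative_position, breaks,
                           rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  hist <- data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
                     density = counts / sum(counts))
  central <- mean(occurrences$relative_position >= 1 / 3 &
                    occurrences$relative_position < 2 / 3)
  list(histogram = hist, central_fraction = central)
}
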