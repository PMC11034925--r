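#' Genomic interval tables
#'
#' Intervals throughout the package are plain data frames with columns
#' `chrom`, `start`, `end` and `strand`, using 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive). Conversions to 1-based conventions
#' happen only at format boundaries (GFF3, AXT).
#'
#' @param chrom character chromosome/sequence names.
#' @param start,end integer 0-based half-open coordinates, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param ... further equal-length columns carried along.
#' @return a data frame of intervals.
#' @export
interval_df <- function(chrom = character(), start = integer(),
                        end = integer(), strand = "+", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$chrom))) stop("interval with empty chrom name")
  bad <- df$start < 0 | df$start >= df$end
  if (any(bad)) stop(sprintf("%d interval(s) violate 0 <= start < end", sum(bad)))
  invisible(df)
}

# IRanges view of an interval df restricted to one chromosome set
.iranges_of <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

#' Which intervals in `a` overlap any interval in `b`
#'
#' Overlap requires the same chromosome and >= 1 bp of shared span;
#' strand is ignored unless `same_strand = TRUE`.
#'
#' @param a,b interval data frames.
#' @param same_strand additionally require equal strand.
#' @return logical vector along rows of `a`.
#' @export
intervals_overlap_any <- function(a, b, same_strand = FALSE) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  out <- rep(FALSE, nrow(a))
  keys_b <- if (same_strand) paste(b$chrom, b$strand) else b$chrom
  keys_a <- if (same_strand) paste(a$chrom, a$strand) else a$chrom
  for (key in unique(keys_a)) {
    ia <- which(keys_a == key); ib <- which(keys_b == key)
    if (!length(ib)) next
    hits <- IRanges::overlapsAny(.iranges_of(a[ia, , drop = FALSE]),
                                 .iranges_of(b[ib, , drop = FALSE]))
    out[ia] <- hits
  }
  out
}

#' Base-pair overlap between two interval sets
#'
#' @param a,b interval data frames.
#' @return total number of bases of `a` covered by the union of `b`.
#' @export
intervals_overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  total <- 0L
  for (chr in unique(a$chrom)) {
    ia <- a[a$chrom == chr, , drop = FALSE]
    ib <- b[b$chrom == chr, , drop = FALSE]
    if (nrow(ib) == 0) next
    cov <- IRanges::intersect(IRanges::reduce(.iranges_of(ia)),
                              IRanges::reduce(.iranges_of(ib)))
    total <- total + sum(IRanges::width(cov))
  }
  total
}

#' Total width of an interval set after merging overlaps
#' @param a interval data frame.
#' @return integer base count.
#' @export
intervals_width <- function(a) {
  if (nrow(a) == 0) return(0L)
  s <- 0L
  for (chr in unique(a$chrom))
    s <- s + sum(IRanges::width(IRanges::reduce(.iranges_of(a[a$chrom == chr, , drop = FALSE]))))
  s
}
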