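#' Multi-species genome container
#'
#' A `genome_set` maps each species id to its sequences (named character
#' vector over `A`, `C`, `G`, `T`, `N`) and annotation interval tables
#' (`exons`, `repeats` and optionally `genes` with a `gene_id` column).
#' Characters outside the alphabet are uppercased and mapped to `N` with a
#' warning, and runs of `N` (hard-masked repeats) are automatically added to
#' the repeat annotation.
#'
#' @param species named list; each element a list with `sequences` and
#'   optionally `exons`, `repeats`, `genes`.
#' @return an object of class `genome_set`.
#' @export
genome_set <- function(species) {
  stopifnot(is.list(species), !is.null(names(species)),
            !anyDuplicated(names(species)))
  out <- lapply(names(species), function(sp) {
    g <- species[[sp]]
    stopifnot(!is.null(g$sequences), !is.null(names(g$sequences)))
    seqs <- toupper(g$sequences)
    nbad <- sum(vapply(seqs, function(s)
      sum(charToRaw(s) %in% charToRaw("ACGTN") == FALSE), integer(1)))
    if (nbad > 0) {
      warning(sprintf("%s: %d base(s) outside ACGTN mapped to N", sp, nbad))
      seqs <- vapply(seqs, function(s)
        gsub("[^ACGTN]", "N", s), character(1))
    }
    lens <- nchar(seqs)
    exons <- g$exons %||% interval_df()
    repeats <- g$repeats %||% interval_df()
    genes <- g$genes %||% NULL
    for (tab in list(exons, repeats, genes)) {
      if (is.null(tab) || nrow(tab) == 0) next
      validate_intervals(tab)
      if (any(is.na(lens[tab$chrom])) || any(tab$end > lens[tab$chrom]))
        stop(sp, ": annotation interval outside its sequence")
    }
    # hard-masked N runs count as repeats
    nr <- lapply(names(seqs), function(chr) {
      m <- gregexpr("N+", seqs[[chr]])[[1]]
      if (m[1] == -1) return(NULL)
      data.frame(chrom = chr, start = as.integer(m) - 1L,
                 end = as.integer(m) + attr(m, "match.length") - 1L,
                 strand = "+", stringsAsFactors = FALSE)
    })
    nr <- do.call(rbind, nr[!vapply(nr, is.null, logical(1))])
    if (!is.null(nr) && nrow(nr))
      repeats <- rbind(repeats[, c("chrom", "start", "end", "strand")],
                       nr)
    list(sequences = seqs, exons = exons, repeats = repeats, genes = genes)
  })
  names(out) <- names(species)
  structure(out, class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set with", length(x), "species\n")
  for (sp in names(x)) {
    g <- x[[sp]]
    cat(sprintf("  %s: %d seq(s), %s bp, %d exon(s), %d repeat(s)\n", sp,
                length(g$sequences), format(sum(nchar(g$sequences)), big.mark = ","),
                nrow(g$exons), nrow(g$repeats)))
  }
  invisible(x)
}

#' Sequence lengths of one species
#' @param gs a `genome_set`.
#' @param sp species id.
#' @return named integer vector of sequence lengths.
#' @export
genome_seqlens <- function(gs, sp) {
  vapply(gs[[sp]]$sequences, nchar, integer(1))
}

#' Extract a subsequence (0-based half-open)
#' @param gs a `genome_set`.
#' @param sp species id.
#' @param chrom sequence name.
#' @param start,end 0-based half-open coordinates.
#' @param strand minus returns the reverse complement.
#' @return character scalar.
#' @export
genome_subseq <- function(gs, sp, chrom, start, end, strand = "+") {
  s <- gs[[sp]]$sequences[[chrom]]
  if (is.null(s)) stop("no sequence ", chrom, " in ", sp)
  stopifnot(start >= 0, end <= nchar(s), start < end)
  x <- substr(s, start + 1L, end)
  if (strand == "-") revcomp(x) else x
}

#' Write one species of a genome set to disk
#'
#' Emits `<sp>.fa`, `<sp>.exons.bed`, `<sp>.repeats.bed` and, when gene
#' annotations are present, `<sp>.genes.gff3`.
#'
#' @param gs a `genome_set`.
#' @param sp species id.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_genome <- function(gs, sp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- gs[[sp]]
  paths <- c(file.path(dir, paste0(sp, ".fa")),
             file.path(dir, paste0(sp, ".exons.bed")),
             file.path(dir, paste0(sp, ".repeats.bed")))
  write_fasta(g$sequences, paths[1])
  ex <- g$exons
  if (!is.null(ex$gene_id)) ex$name <- ex$gene_id
  write_bed(ex, paths[2])
  write_bed(g$repeats, paths[3])
  if (!is.null(g$genes) && nrow(g$genes)) {
    p <- file.path(dir, paste0(sp, ".genes.gff3"))
    ex <- g$exons
    if (is.null(ex$gene_id)) ex$gene_id <- NA_character_
    write_gff3(g$genes, ex, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
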