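#' Read a FASTA file
#'
#' Returns sequences as a named character vector with case preserved.
#' Records with empty sequences and malformed headers are rejected.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) && !startsWith(lines[nonempty[1]], ">"))
    stop(sprintf("malformed FASTA header at line %d of %s", nonempty[1], path))
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA (", path, "): ",
                                            conditionMessage(e)))
  if (any(Biostrings::width(seqs) == 0)) {
    bad <- names(seqs)[Biostrings::width(seqs) == 0][1]
    stop(sprintf("empty sequence record '%s' in %s", bad, path))
  }
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (any(!nzchar(seqs))) stop("refusing to write empty sequence record")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a BED file (3+ columns)
#'
#' BED intervals are 0-based half-open and are taken verbatim. Rows with
#' `start >= end` are dropped with a logged warning.
#'
#' @param path BED file.
#' @return interval data frame with optional `name` and `score` columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#"),
                  error = function(e) {
                    if (grepl("no lines available", conditionMessage(e)))
                      return(NULL)
                    stop(e)
                  })
  if (is.null(raw)) return(interval_df())
  if (ncol(raw) < 3) stop("BED needs >= 3 columns: ", path)
  df <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
                   strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else "+",
                   stringsAsFactors = FALSE)
  if (ncol(raw) >= 4) df$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) df$score <- raw[[5]]
  bad <- df$start >= df$end | df$start < 0
  if (any(bad)) {
    cne_log(sprintf("read_bed: dropped %d row(s) with start >= end in %s",
                    sum(bad), path), level = "warn")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' Writes BED6 when `name` is present (score defaults to 0), else BED3.
#'
#' @param df interval data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  out <- df[, c("chrom", "start", "end")]
  if (!is.null(df$name)) {
    out$name <- df$name
    out$score <- df$score %||% 0
    out$strand <- df$strand %||% "+"
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read exon (or other feature) intervals from GFF3
#'
#' GFF3 is 1-based inclusive; returned intervals are 0-based half-open.
#' Rows whose converted interval is empty are dropped with a logged warning.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (column 3), default `"exon"`.
#' @return interval data frame with `id` and `parent` attribute columns.
#' @export
read_gff3_exons <- function(path, feature = "exon") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE,
                    col.names = c("seqid", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attributes"))
  raw <- raw[raw$type == feature, , drop = FALSE]
  attr_field <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  df <- data.frame(chrom = raw$seqid,
                   start = as.integer(raw$start) - 1L,  # to 0-based half-open
                   end = as.integer(raw$end),
                   strand = ifelse(raw$strand %in% c("+", "-"), raw$strand, "+"),
                   id = attr_field(raw$attributes, "ID"),
                   parent = attr_field(raw$attributes, "Parent"),
                   stringsAsFactors = FALSE)
  bad <- df$start >= df$end | df$start < 0
  if (any(bad)) {
    cne_log(sprintf("read_gff3_exons: dropped %d malformed row(s) in %s",
                    sum(bad), path), level = "warn")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write gene/exon annotations as GFF3
#'
#' @param genes interval data frame with a `gene_id` column.
#' @param exons interval data frame with a `gene_id` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(df, type, attr)
    sprintf("%s\tcnevol\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$chrom, type, df$start + 1L, df$end, df$strand, attr)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(fmt(g, "gene", sprintf("ID=%s", g$gene_id)), con)
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(ex))
      writeLines(fmt(ex, "exon", sprintf("ID=%s.e%d;Parent=%s", ex$gene_id,
                                         seq_len(nrow(ex)), ex$gene_id)), con)
  }
  invisible(path)
}

#' Read pairwise alignment blocks from AXT
#'
#' AXT coordinates are 1-based inclusive; minus-strand query coordinates are
#' given on the reverse-complemented query sequence. Internally blocks are
#' 0-based half-open with query intervals normalised to the forward strand
#' (this requires `query_seqlens` when minus-strand blocks are present).
#'
#' @param path AXT file.
#' @param query_seqlens named integer vector of query sequence lengths.
#' @return alignment block data frame (see [seed_extend_align()]).
#' @export
read_axt <- function(path, query_seqlens = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  # records are triplets: header, ref alignment row, query alignment row
  body <- lines[nzchar(lines)]
  if (length(body) %% 3 != 0)
    stop("malformed AXT (records are not triplets): ", path)
  n <- length(body) / 3
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- strsplit(body[3 * i - 2], "\\s+")[[1]]
    if (length(hdr) != 9) stop("malformed AXT header in record ", i)
    ref_aln <- toupper(body[3 * i - 1]); query_aln <- toupper(body[3 * i])
    if (nchar(ref_aln) != nchar(query_aln))
      stop(sprintf("AXT record %d: aligned rows differ in length", i))
    strand <- hdr[8]
    rs <- as.integer(hdr[3]) - 1L; re <- as.integer(hdr[4])
    qs <- as.integer(hdr[6]) - 1L; qe <- as.integer(hdr[7])
    qchrom <- hdr[5]
    if (strand == "-") {
      if (is.null(query_seqlens) || is.na(query_seqlens[qchrom]))
        stop("minus-strand AXT block needs query_seqlens for ", qchrom)
      L <- query_seqlens[[qchrom]]
      tmp <- qs; qs <- L - qe; qe <- L - tmp
    }
    if (nchar(gsub("-", "", ref_aln)) != re - rs ||
        nchar(gsub("-", "", query_aln)) != qe - qs)
      stop(sprintf("AXT record %d: sequence length mismatch with coordinates", i))
    out[[i]] <- data.frame(ref_chrom = hdr[2], ref_start = rs, ref_end = re,
                           query_chrom = qchrom, query_start = qs, query_end = qe,
                           strand = strand, score = as.numeric(hdr[9]),
                           ref_aln = ref_aln, query_aln = query_aln,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write alignment blocks as AXT
#'
#' Inverse of [read_axt()]: internal forward-strand query coordinates of
#' minus-strand blocks are converted back to AXT's reverse-complement
#' convention.
#'
#' @param blocks alignment block data frame.
#' @param path output file.
#' @param query_seqlens named integer vector of query sequence lengths
#'   (needed for minus-strand blocks).
#' @return `path`, invisibly.
#' @export
write_axt <- function(blocks, path, query_seqlens = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    qs <- b$query_start; qe <- b$query_end
    if (b$strand == "-") {
      if (is.null(query_seqlens) || is.na(query_seqlens[b$query_chrom]))
        stop("minus-strand block needs query_seqlens for ", b$query_chrom)
      L <- query_seqlens[[b$query_chrom]]
      tmp <- qs; qs <- L - qe; qe <- L - tmp
    }
    writeLines(sprintf("%d %s %d %d %s %d %d %s %d", i - 1L,
                       b$ref_chrom, b$ref_start + 1L, b$ref_end,
                       b$query_chrom, qs + 1L, qe, b$strand,
                       as.integer(round(b$score))), con)
    writeLines(c(b$ref_aln, b$query_aln, ""), con)
  }
  invisible(path)
}

#' Read / write an orthology table
#'
#' TSV with columns `species_id`, `gene_id`, `orthogroup_id`,
#' `paralog_partner_ids` (comma separated, may be empty) and
#' `paralog_origin` (`pre-WGD`, `post-WGD` or `none`).
#'
#' @param path TSV file.
#' @return data frame with the columns above.
#' @export
read_orthology <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("species_id", "gene_id", "orthogroup_id",
            "paralog_partner_ids", "paralog_origin")
  if (!all(need %in% names(df))) stop("orthology table missing columns")
  if (anyDuplicated(df[c("species_id", "gene_id")]))
    stop("orthology table has duplicated (species_id, gene_id)")
  df$paralog_partner_ids[is.na(df$paralog_partner_ids)] <- ""
  df
}

#' @rdname read_orthology
#' @param df orthology data frame.
#' @export
write_orthology <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Species tree with designated clades and outgroups
#'
#' Wraps an `ape::phylo` tree together with the two basally splitting clades
#' used for ancestral-repertoire inference, the ray-finned outgroup
#' (gar analog) and the more distant vertebrate outgroups.
#'
#' @param phylo an `ape::phylo` object with branch lengths.
#' @param clade1,clade2 character vectors of tip labels (disjoint, non-empty).
#' @param outgroup_ids gar-analog tip labels.
#' @param vertebrate_ids vertebrate outgroup tip labels.
#' @return an object of class `species_tree`.
#' @export
species_tree <- function(phylo, clade1, clade2, outgroup_ids = character(),
                         vertebrate_ids = character()) {
  stopifnot(inherits(phylo, "phylo"), length(clade1) > 0, length(clade2) > 0)
  if (length(intersect(clade1, clade2)))
    stop("clade1 and clade2 must be disjoint")
  tips <- phylo$tip.label
  missing <- setdiff(c(clade1, clade2, outgroup_ids, vertebrate_ids), tips)
  if (length(missing)) stop("not tree leaves: ", paste(missing, collapse = ", "))
  structure(list(phylo = phylo, clade1 = clade1, clade2 = clade2,
                 outgroup_ids = outgroup_ids, vertebrate_ids = vertebrate_ids),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", length(x$phylo$tip.label), "tips\n")
  cat("  clade1:", paste(x$clade1, collapse = ", "), "\n")
  cat("  clade2:", paste(x$clade2, collapse = ", "), "\n")
  cat("  outgroup:", paste(x$outgroup_ids, collapse = ", "),
      " vertebrates:", paste(x$vertebrate_ids, collapse = ", "), "\n")
  invisible(x)
}
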