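#' Project per-species hit sequences into a CNE's coordinate frame
#'
#' For substitution-only cohorts hits are ungapped, so the best-hit
#' coordinates define an exact offset map between the query element and each
#' genome. The returned sequences all have length
#' `element length + 2 * flank`; positions outside the chromosome (or not
#' covered) are padded with `-`. Minus-strand hits are reverse-complemented
#' into the element's orientation.
#'
#' @param cne one-row CNE data frame.
#' @param presence_rows presence-matrix rows for that CNE.
#' @param genomes a [genome_set()].
#' @param flank bp of flanking sequence on each side.
#' @return named character vector keyed by species.
#' @export
marker_frame_sequences <- function(cne, presence_rows, genomes, flank = 50L) {
  L <- cne$end - cne$start
  frame_len <- L + 2L * flank
  out <- character(0)
  for (j in seq_len(nrow(presence_rows))) {
    h <- presence_rows[j, ]
    lens <- genome_seqlens(genomes, h$species_id)
    clen <- lens[[h$chrom]]
    if (h$strand == "+") {
      gs <- h$start - h$q_cov_start - flank
      ge <- gs + frame_len
      s <- genome_subseq(genomes, h$species_id, h$chrom,
                         max(0L, gs), min(clen, ge))
      pad_l <- max(0L, -gs); pad_r <- max(0L, ge - clen)
    } else {
      gs <- h$end + h$q_cov_start - L - flank
      ge <- h$end + h$q_cov_start + flank
      s <- genome_subseq(genomes, h$species_id, h$chrom,
                         max(0L, gs), min(clen, ge), strand = "-")
      pad_l <- max(0L, ge - clen); pad_r <- max(0L, -gs)
    }
    out[[h$species_id]] <- paste0(strrep("-", pad_l), s, strrep("-", pad_r))
  }
  out
}

#' Universal single-copy marker selection
#'
#' Keeps CNEs with exactly one hit in every species of `species_subset`
#' (best-hit search masks true copy number, so counts come from a
#' copy-number table built with [count_hits()]).
#'
#' @param hit_counts data frame `cne_id` x species columns of hit counts
#'   (see [count_hits_matrix()]).
#' @param species_subset species that must carry exactly one copy.
#' @return character vector of marker CNE ids.
#' @export
universal_single_copy <- function(hit_counts, species_subset) {
  stopifnot(all(species_subset %in% names(hit_counts)))
  m <- as.matrix(hit_counts[, species_subset, drop = FALSE])
  hit_counts$cne_id[rowSums(m == 1L) == length(species_subset)]
}

#' Hit-count table of CNEs across genomes
#'
#' @param cnes CNE set data frame.
#' @param genomes a [genome_set()].
#' @param params a [search_params()].
#' @return data frame with `cne_id` and one count column per species
#'   (the reference species uses its own coordinates, count >= 1).
#' @export
count_hits_matrix <- function(cnes, genomes, params = search_params()) {
  seqs <- cne_sequences(cnes, genomes)
  out <- data.frame(cne_id = cnes$id, stringsAsFactors = FALSE)
  for (sp in names(genomes))
    out[[sp]] <- unname(count_hits(seqs, genomes[[sp]], params, sp))
  out
}

#' Extract flanked marker sequences for a set of CNEs
#'
#' Best-hit coordinates extended by `flank` bp on each side, clipped at
#' chromosome ends; minus-strand hits are reverse-complemented into marker
#' orientation.
#'
#' @param cne_ids marker ids.
#' @param cnes CNE set data frame (for the reference coordinates).
#' @param presence presence matrix.
#' @param genomes a [genome_set()].
#' @param flank bp of flank on each side (default 50).
#' @return named list: marker id -> named character vector per species.
#' @export
extract_marker_seqs <- function(cne_ids, cnes, presence, genomes, flank = 50L) {
  out <- lapply(cne_ids, function(id) {
    rows <- presence[presence$query_id == id, , drop = FALSE]
    marker_frame_sequences(cnes[cnes$id == id, ], rows, genomes, flank)
  })
  names(out) <- cne_ids
  out
}

#' Concatenate markers into a trimmed supermatrix
#'
#' Per-marker sequences must be aligned (equal lengths); in
#' substitution-only cohorts the frame projection guarantees this, and an
#' external MSA hook (`msa_fun`, FASTA-in/FASTA-out semantics: a function
#' from a named character vector to an aligned named character vector) can
#' be supplied otherwise. Species missing from a marker are padded with
#' gaps; columns with a gap fraction above `gap_threshold` are removed.
#'
#' @param marker_seqs list from [extract_marker_seqs()].
#' @param gap_threshold columns with `> gap_threshold` gap fraction are
#'   trimmed (default 0.5).
#' @param msa_fun optional aligner hook applied to unequal-length markers.
#' @return list of class `supermatrix`: `matrix` (species x columns
#'   character matrix) and `partitions` (marker -> retained column range).
#' @export
build_supermatrix <- function(marker_seqs, gap_threshold = 0.5, msa_fun = NULL) {
  stopifnot(length(marker_seqs) > 0)
  species <- sort(unique(unlist(lapply(marker_seqs, names))))
  cols <- list(); parts <- list(); at <- 0L
  for (mk in names(marker_seqs)) {
    seqs <- marker_seqs[[mk]]
    if (length(unique(nchar(seqs))) != 1) {
      if (is.null(msa_fun))
        stop("marker ", mk, " has unaligned unequal lengths and no MSA hook")
      seqs <- msa_fun(seqs)
      if (length(unique(nchar(seqs))) != 1)
        stop("MSA hook returned unequal lengths for marker ", mk)
    }
    w <- nchar(seqs[[1]])
    m <- matrix("-", nrow = length(species), ncol = w,
                dimnames = list(species, NULL))
    for (sp in names(seqs)) m[sp, ] <- strsplit(seqs[[sp]], "")[[1]]
    gapfrac <- colMeans(m == "-")
    keep <- gapfrac <= gap_threshold
    m <- m[, keep, drop = FALSE]
    if (ncol(m)) {
      cols[[mk]] <- m
      parts[[mk]] <- data.frame(marker = mk, start = at + 1L,
                                end = at + ncol(m), stringsAsFactors = FALSE)
      at <- at + ncol(m)
    }
  }
  mat <- do.call(cbind, cols)
  partitions <- do.call(rbind, parts)
  rownames(partitions) <- NULL
  structure(list(matrix = mat, partitions = partitions), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", nrow(x$matrix), "species x", ncol(x$matrix),
      "columns;", nrow(x$partitions), "marker partition(s)\n")
  invisible(x)
}

#' Write a supermatrix as relaxed PHYLIP plus a partition TSV
#' @param sm a `supermatrix`.
#' @param path PHYLIP output path; partitions go to `<path>.partitions.tsv`.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(sm$matrix), ncol(sm$matrix)), con)
  for (sp in rownames(sm$matrix))
    writeLines(paste0(sp, "  ", paste(sm$matrix[sp, ], collapse = "")), con)
  write.table(sm$partitions, paste0(path, ".partitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Neighbor-joining tree from a supermatrix
#'
#' Distances are p-distances with pairwise deletion (gap/`N` sites skipped
#' per pair); `correction = "JC69"` applies the Jukes-Cantor correction.
#' All-gap species are excluded with a warning.
#'
#' @param sm a `supermatrix`.
#' @param correction `"raw"` (default) or `"JC69"`.
#' @return an `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(sm, correction = c("raw", "JC69")) {
  correction <- match.arg(correction)
  m <- sm$matrix
  allgap <- rowMeans(m == "-" | m == "N") == 1
  if (any(allgap)) {
    warning("excluding all-gap species: ",
            paste(rownames(m)[allgap], collapse = ", "))
    m <- m[!allgap, , drop = FALSE]
  }
  if (nrow(m) < 4) stop("need >= 4 species for NJ")
  bin <- ape::as.DNAbin(tolower(m))
  d <- ape::dist.dna(bin, model = if (correction == "raw") "raw" else "JC69",
                     pairwise.deletion = TRUE)
  ape::nj(d)
}

#' Robinson-Foulds distance between two unrooted topologies
#' @param t1,t2 `ape::phylo` trees.
#' @return integer RF distance (0 means identical topology).
#' @export
rf_distance <- function(t1, t2) {
  as.integer(ape::dist.topo(ape::unroot(t1), ape::unroot(t2), method = "PH85"))
}
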