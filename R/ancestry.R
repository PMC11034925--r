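#' Parameters for ancestral-repertoire inference and zone profiling
#'
#' @param clade1,clade2 the two basally splitting clades (species ids).
#' @param neopterygian_outgroup gar-analog species ids.
#' @param vertebrate_outgroup vertebrate outgroup species ids (disjoint from
#'   the clades and the gar analog).
#' @param zone_size genomic window size (bp) for zone profiling.
#' @return list of class `ancestry_params`.
#' @export
ancestry_params <- function(clade1, clade2, neopterygian_outgroup,
                            vertebrate_outgroup, zone_size = 500000L) {
  stopifnot(length(clade1) > 0, length(clade2) > 0, zone_size > 0,
            !any(c(neopterygian_outgroup, vertebrate_outgroup) %in%
                   c(clade1, clade2)))
  structure(list(clade1 = clade1, clade2 = clade2,
                 neopterygian_outgroup = neopterygian_outgroup,
                 vertebrate_outgroup = vertebrate_outgroup,
                 zone_size = as.integer(zone_size)),
            class = "ancestry_params")
}

#' Infer the ancestral CNE set from the two basal clades
#'
#' Elements detected in the clade-1 reference pair (zCNE analog) are kept
#' when present in at least one clade-2 species; elements from the clade-2
#' reference pair (fCNE analog) are kept when present in at least one
#' clade-1 species and not overlapping any kept clade-1 element. Overlap is
#' tested first in the clade-1 reference species via the element's best hit
#' there (>= 1 bp same-strand overlap), falling back to any shared species.
#' Such elements were necessarily inherited from the common ancestor of
#' both clades.
#'
#' @param zcne_set,fcne_set CNE set data frames from the two focal pairs.
#' @param presence a presence matrix covering both sets over all species.
#' @param params an [ancestry_params()].
#' @return the combined ancestral set with `source_set` and clade-support
#'   columns.
#' @export
infer_ancestral_set <- function(zcne_set, fcne_set, presence, params) {
  stopifnot(inherits(params, "ancestry_params"))
  support <- function(ids, clade) {
    vapply(ids, function(id)
      length(intersect(presence_species(presence, id), clade)), integer(1))
  }
  z2 <- support(zcne_set$id, params$clade2)
  z1 <- support(zcne_set$id, params$clade1)
  keep_z <- zcne_set[z2 >= 1, , drop = FALSE]
  keep_z$source_set <- "zCNE"
  keep_z$n_clade1_present <- z1[z2 >= 1]
  keep_z$n_clade2_present <- z2[z2 >= 1]
  f1 <- support(fcne_set$id, params$clade1)
  f2 <- support(fcne_set$id, params$clade2)
  cand_f <- fcne_set[f1 >= 1, , drop = FALSE]
  # overlap-dedup against kept clade-1 elements
  zref <- unique(zcne_set$ref_species)
  overlaps <- rep(FALSE, nrow(cand_f))
  shared_species <- unique(presence$species_id)
  test_order <- c(zref, setdiff(shared_species, zref))
  for (i in seq_len(nrow(cand_f))) {
    fhits <- presence[presence$query_id == cand_f$id[i], , drop = FALSE]
    for (sp in test_order) {
      fh <- fhits[fhits$species_id == sp, , drop = FALSE]
      if (nrow(fh) == 0) next
      zh <- presence[presence$species_id == sp &
                       presence$query_id %in% keep_z$id, , drop = FALSE]
      if (nrow(zh) == 0) next
      if (any(intervals_overlap_any(
        interval_df(fh$chrom, fh$start, fh$end, fh$strand),
        interval_df(zh$chrom, zh$start, zh$end, zh$strand),
        same_strand = TRUE))) {
        overlaps[i] <- TRUE
      }
      break  # decided in the first shared species with a hit
    }
  }
  keep_f <- cand_f[!overlaps, , drop = FALSE]
  if (nrow(keep_f)) {
    keep_f$source_set <- "fCNE"
    keep_f$n_clade1_present <- f1[match(keep_f$id, fcne_set$id)]
    keep_f$n_clade2_present <- f2[match(keep_f$id, fcne_set$id)]
  } else {
    keep_f <- keep_z[0, , drop = FALSE]
  }
  out <- rbind(keep_z, keep_f)
  rownames(out) <- NULL
  out
}

#' Assign origin categories from outgroup presence
#'
#' A hit in any vertebrate outgroup makes an element `vertebrate`-age;
#' otherwise a hit in the gar analog makes it `neopterygian`; otherwise it
#' is `3R` (teleost specific).
#'
#' @param atcnes ancestral set from [infer_ancestral_set()].
#' @param presence presence matrix including the outgroup species.
#' @param params an [ancestry_params()].
#' @return `atcnes` with an `origin_category` column.
#' @export
categorize_origin <- function(atcnes, presence, params) {
  cat <- vapply(atcnes$id, function(id) {
    sp <- presence_species(presence, id)
    if (length(intersect(sp, params$vertebrate_outgroup))) "vertebrate"
    else if (length(intersect(sp, params$neopterygian_outgroup))) "neopterygian"
    else "3R"
  }, character(1))
  atcnes$origin_category <- unname(cat)
  atcnes
}

#' Per-species loss rates by origin category
#'
#' For each species, the number of ancestral elements of each category with
#' no hit there, expressed as a percentage of the total ancestral set (the
#' convention used for loss heatmaps).
#'
#' @param atcnes categorized ancestral set.
#' @param presence presence matrix.
#' @param species species to tabulate (default: all in the matrix).
#' @return data frame with per-category absent counts and percentages plus
#'   totals.
#' @export
loss_rates <- function(atcnes, presence, species = NULL) {
  species <- species %||% sort(unique(presence$species_id))
  total <- nrow(atcnes)
  cats <- c("vertebrate", "neopterygian", "3R")
  out <- lapply(species, function(sp) {
    present_ids <- presence$query_id[presence$species_id == sp]
    absent <- atcnes[!(atcnes$id %in% present_ids), , drop = FALSE]
    counts <- vapply(cats, function(cc) sum(absent$origin_category == cc),
                     integer(1))
    data.frame(species_id = sp,
               absent_vertebrate = counts[1], absent_neopterygian = counts[2],
               absent_3r = counts[3], absent_total = sum(counts),
               pct_vertebrate = 100 * counts[1] / total,
               pct_neopterygian = 100 * counts[2] / total,
               pct_3r = 100 * counts[3] / total,
               pct_total = 100 * sum(counts) / total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Profile ancestral elements over fixed-size genomic zones
#'
#' Tiles each reference chromosome into `zone_size` windows (the final
#' partial window counts as a zone), assigns each mapped element to the zone
#' containing its start, and classifies zones: `empty` (no element),
#' `novel-3R` (3R present, no older category), `novel-neopterygian`
#' (neopterygian present, no vertebrate), else `vertebrate-containing`.
#' Elements anchored on another reference are mapped through their best hit
#' in `reference` and dropped (with a log line) when absent there.
#'
#' @param atcnes categorized ancestral set.
#' @param genomes a [genome_set()].
#' @param reference reference species for the zone map.
#' @param params an [ancestry_params()].
#' @param presence presence matrix (needed to map foreign-reference
#'   elements).
#' @return data frame of zones with per-category counts and a `class`
#'   column; attribute `n_mapped` records how many elements were mapped.
#' @export
zone_profile <- function(atcnes, genomes, reference, params, presence = NULL) {
  seqlens <- genome_seqlens(genomes, reference)
  pos <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(atcnes))) {
    if (atcnes$ref_species[i] == reference) {
      pos[[length(pos) + 1L]] <- data.frame(chrom = atcnes$chrom[i],
                                            start = atcnes$start[i],
                                            category = atcnes$origin_category[i],
                                            stringsAsFactors = FALSE)
    } else if (!is.null(presence)) {
      h <- presence[presence$query_id == atcnes$id[i] &
                      presence$species_id == reference, , drop = FALSE]
      if (nrow(h)) {
        pos[[length(pos) + 1L]] <- data.frame(chrom = h$chrom[1],
                                              start = h$start[1],
                                              category = atcnes$origin_category[i],
                                              stringsAsFactors = FALSE)
      } else n_dropped <- n_dropped + 1L
    } else n_dropped <- n_dropped + 1L
  }
  if (n_dropped)
    cne_log(sprintf("zone_profile: %d element(s) not mappable to %s",
                    n_dropped, reference))
  pos <- if (length(pos)) do.call(rbind, pos) else
    data.frame(chrom = character(), start = integer(), category = character())
  if (nrow(pos) && (any(is.na(seqlens[pos$chrom])) ||
                    any(pos$start >= seqlens[pos$chrom])))
    stop("element beyond chromosome length: corrupt input")
  zones <- do.call(rbind, lapply(names(seqlens), function(chr) {
    n <- max(1L, as.integer(ceiling(seqlens[[chr]] / params$zone_size)))
    data.frame(chrom = chr,
               start = (seq_len(n) - 1L) * params$zone_size,
               end = pmin(seq_len(n) * params$zone_size, seqlens[[chr]]),
               stringsAsFactors = FALSE)
  }))
  zi <- match(paste(pos$chrom, pos$start %/% params$zone_size),
              paste(zones$chrom, (zones$start %/% params$zone_size)))
  for (cc in c("vertebrate", "neopterygian", "3R")) {
    counts <- table(factor(zi[pos$category == cc], levels = seq_len(nrow(zones))))
    zones[[paste0("n_", sub("3R", "3r", cc))]] <- as.integer(counts)
  }
  zones$class <- with(zones, ifelse(
    n_vertebrate + n_neopterygian + n_3r == 0, "empty",
    ifelse(n_vertebrate > 0, "vertebrate-containing",
           ifelse(n_neopterygian > 0, "novel-neopterygian", "novel-3R"))))
  attr(zones, "n_mapped") <- nrow(pos)
  zones
}

#' Mean cross-species conservation score of ancestral elements
#'
#' For each element, sequences of all present species are projected into the
#' element's coordinate frame and the mean pairwise identity over species
#' pairs is reported (a column-identity stand-in for model-based
#' conservation scores). Elements present in fewer than two species get
#' `NA`.
#'
#' @param atcnes categorized ancestral set.
#' @param presence presence matrix.
#' @param genomes a [genome_set()].
#' @return `atcnes` with a `conservation_score` column.
#' @export
conservation_score <- function(atcnes, presence, genomes) {
  scores <- vapply(seq_len(nrow(atcnes)), function(i) {
    rows <- presence[presence$query_id == atcnes$id[i], , drop = FALSE]
    if (nrow(rows) < 2) return(NA_real_)
    seqs <- marker_frame_sequences(atcnes[i, ], rows, genomes, flank = 0L)
    m <- do.call(rbind, strsplit(seqs, ""))
    pairs <- utils::combn(nrow(m), 2)
    mean(apply(pairs, 2, function(p) {
      a <- m[p[1], ]; b <- m[p[2], ]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      if (!any(ok)) return(NA_real_)
      mean(a[ok] == b[ok])
    }), na.rm = TRUE)
  }, numeric(1))
  atcnes$conservation_score <- scores
  atcnes
}
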