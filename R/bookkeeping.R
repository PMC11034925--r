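#' Bookkeeping summaries of an ancestral CNE repertoire
#'
#' Small arithmetic helpers used both on pipeline outputs and on externally
#' reported count tables: the origin-category partition (which must be
#' exhaustive and disjoint, so category counts add up to the repertoire
#' size), gained-element shares among post-vertebrate categories, zone
#' occupancy, and paralog-cluster origin shares.
#'
#' @param counts named numeric vector with elements `vertebrate`,
#'   `neopterygian` and `3R`.
#' @return `category_partition()`: list with `total` and per-category
#'   percentages of the total.
#' @export
category_partition <- function(counts) {
  stopifnot(all(c("vertebrate", "neopterygian", "3R") %in% names(counts)))
  counts <- counts[c("vertebrate", "neopterygian", "3R")]
  total <- sum(counts)
  list(total = total, pct = 100 * counts / total)
}

#' @rdname category_partition
#' @param neopterygian,gained_3r counts of elements gained in the
#'   Neopterygian ancestor and after the gar split.
#' @return `gained_shares()`: percentages of all gained elements per class.
#' @export
gained_shares <- function(neopterygian, gained_3r) {
  total <- neopterygian + gained_3r
  c(neopterygian = 100 * neopterygian / total,
    `3R` = 100 * gained_3r / total)
}

#' @rdname category_partition
#' @param n_occupied,n_empty zone counts with and without any ancestral
#'   element.
#' @return `zone_occupancy()`: list with `total` zones and `pct_empty`.
#' @export
zone_occupancy <- function(n_occupied, n_empty) {
  total <- n_occupied + n_empty
  list(total = total, pct_empty = 100 * n_empty / total)
}

#' @rdname category_partition
#' @param n_pre,n_post paralogous element counts in pre-WGD (2R-derived) and
#'   post-WGD (3R-derived) clusters.
#' @return `paralog_origin_shares()`: list with `total` and percentages.
#' @export
paralog_origin_shares <- function(n_pre, n_post) {
  total <- n_pre + n_post
  list(total = total,
       pct_pre = 100 * n_pre / total,
       pct_post = 100 * n_post / total)
}

#' Summarise a zone profile table
#'
#' @param zones output of [zone_profile()].
#' @return list with total zones, occupied/empty counts, per-category
#'   occupied-zone counts and the empty percentage.
#' @export
zone_class_summary <- function(zones) {
  occupied <- sum(zones$class != "empty")
  empty <- sum(zones$class == "empty")
  list(total = nrow(zones), occupied = occupied, empty = empty,
       pct_empty = zone_occupancy(occupied, empty)$pct_empty,
       zones_with_vertebrate = sum(zones$n_vertebrate > 0),
       zones_with_neopterygian = sum(zones$n_neopterygian > 0),
       zones_with_3r = sum(zones$n_3r > 0),
       novel_neopterygian = sum(zones$class == "novel-neopterygian"),
       novel_3r = sum(zones$class == "novel-3R"))
}
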