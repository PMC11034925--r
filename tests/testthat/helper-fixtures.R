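# shared fixtures, memoised so expensive cohorts are built once per test run
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small seven-species cohort used across module tests (fast, ~5 s)
small_sim_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, n_chrom = 2L, chrom_length = 200000L,
               n_genes = 40L, n_cne_vertebrate = 10L, n_cne_neopterygian = 8L,
               n_cne_3r = 12L, n_anchor_ancestral = 6L, n_anchor_novel = 2L,
               n_pre_wgd_pairs = 1L, n_repeat_copies = 10L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

small_cohort <- function() memo("small_cohort", simulate_cohort(small_sim_config()))

# loss-free, inversion-free, fully-retained cohort (exact bookkeeping cases)
noloss_cohort <- function() memo("noloss_cohort", simulate_cohort(
  small_sim_config(seed = 3, loss_prob_per_branch = 0, wgd_retention = 1,
                   wgd_retention_genes = 1, inversion_rate = 0)))

# full pipeline on the small cohort (shared by several module tests)
small_run <- function() memo("small_run", {
  run_pipeline(pipeline_config(seed = 7L, sim = small_sim_config()))
})

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# plant a copy of `segment` at `at` (0-based) in `host`, with per-base
# substitution probability `mut`
plant <- function(host, segment, at, mut = 0) {
  chars <- strsplit(segment, "")[[1]]
  if (mut > 0) {
    hit <- which(runif(length(chars)) < mut)
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  }
  paste0(substr(host, 1, at), paste(chars, collapse = ""),
         substr(host, at + nchar(segment) + 1L, nchar(host)))
}

# brute-force window scanner: O(L * W) explicit loop (independent oracle)
brute_window_scan <- function(status, window, min_matches) {
  n <- length(status)
  marked <- rep(FALSE, n)
  if (n >= window) {
    for (w in seq_len(n - window + 1L)) {
      cols <- w:(w + window - 1L)
      if (any(status[cols] < 0)) next
      if (sum(status[cols]) >= min_matches) marked[cols] <- TRUE
    }
  }
  marked
}

# brute-force best collinear chain score by exhaustive subset enumeration
brute_best_chain <- function(blocks, gap_open = 50, per_bp = 0.5,
                             max_gap = 10000) {
  n <- nrow(blocks)
  blocks <- blocks[order(blocks$ref_start, blocks$query_start), , drop = FALSE]
  best <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx)) next
    ok <- TRUE
    sc <- sum(blocks$score[idx])
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1L)) {
        j <- idx[k]; i <- idx[k + 1L]
        rgap <- blocks$ref_start[i] - blocks$ref_end[j]
        qgap <- blocks$query_start[i] - blocks$query_end[j]
        if (rgap < 0 || qgap < 0 || rgap > max_gap || qgap > max_gap) {
          ok <- FALSE; break
        }
        sc <- sc - gap_open - per_bp * (rgap + qgap)
      }
    }
    if (ok && sc > best) best <- sc
  }
  best
}
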