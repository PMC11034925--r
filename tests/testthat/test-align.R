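test_that("an exact copy of a reference region yields one full-identity block", {
  set.seed(1)
  ref <- list(sequences = c(chrR = random_dna(4000L)))
  segment <- substr(ref$sequences[["chrR"]], 1001, 1500)
  qseq <- plant(random_dna(3000L), segment, 800L)
  query <- list(sequences = c(chrQ = qseq))
  blocks <- seed_extend_align(ref, query)
  hit <- blocks[blocks$strand == "+" &
                  blocks$ref_start <= 1000 & blocks$ref_end >= 1500, ]
  expect_gte(nrow(hit), 1)
  expect_true(any(block_identity(hit) == 1))
  expect_true(any(hit$query_start <= 800 & hit$query_end >= 1300))
})

test_that("a reverse-complement copy yields one minus-strand block", {
  set.seed(2)
  ref <- list(sequences = c(chrR = random_dna(4000L)))
  segment <- substr(ref$sequences[["chrR"]], 2001, 2400)
  qseq <- plant(random_dna(3000L), revcomp(segment), 1200L)
  query <- list(sequences = c(chrQ = qseq))
  blocks <- seed_extend_align(ref, query)
  hit <- blocks[blocks$strand == "-", ]
  expect_gte(nrow(hit), 1)
  best <- hit[which.max(hit$score), ]
  # forward-strand query interval maps back to the planted copy
  expect_lte(abs(best$query_start - 1200L), 5)
  expect_identical(gsub("-", "", best$query_aln),
                   revcomp(substr(qseq, best$query_start + 1, best$query_end)))
})

test_that("diverged planted homologies are recovered and agree with Smith-Waterman", {
  set.seed(3)
  for (case in 1:2) {
    refseq <- random_dna(50000L)
    qhost <- random_dna(50000L)
    pos_r <- c(12000L, 30000L); pos_q <- c(5000L, 42000L)
    segs <- lapply(pos_r, function(p) substr(refseq, p + 1, p + 300))
    for (k in 1:2) qhost <- plant(qhost, segs[[k]], pos_q[k], mut = 0.15)
    ref <- list(sequences = c(r = refseq))
    query <- list(sequences = c(q = qhost))
    blocks <- seed_extend_align(ref, query)
    for (k in 1:2) {
      got <- blocks[blocks$ref_start < pos_r[k] + 300 & blocks$ref_end > pos_r[k], ]
      expect_gte(nrow(got), 1)
      # oracle: exhaustive local alignment of the planted pair
      sw <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(segs[[k]]),
        Biostrings::DNAString(substr(qhost, pos_q[k] + 1, pos_q[k] + 300)),
        type = "local", substitutionMatrix =
          Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2),
        gapOpening = 5, gapExtension = 2)
      expect_gte(max(got$score), 0.8 * Biostrings::score(sw))
    }
  }
})

test_that("round 2 equals a single round on manually masked input", {
  set.seed(4)
  refseq <- random_dna(20000L)
  seg <- substr(refseq, 5001, 5400)
  qseq <- plant(plant(random_dna(20000L), seg, 2000L, mut = 0.05),
                seg, 12000L, mut = 0.05)
  ref <- list(sequences = c(r = refseq))
  query <- list(sequences = c(q = qseq))
  two <- two_round_align(ref, query)
  r1 <- two[two$round == 1L, ]
  r2 <- two[two$round == 2L, ]
  # oracle: mask round-1 footprints by hand and run a single round
  mask <- function(s, ints) {
    for (i in seq_len(nrow(ints)))
      substr(s, ints$start[i] + 1L, ints$end[i]) <-
        strrep("N", ints$end[i] - ints$start[i])
    s
  }
  mref <- list(sequences = c(r = mask(refseq, data.frame(start = r1$ref_start,
                                                         end = r1$ref_end))))
  mq <- list(sequences = c(q = mask(qseq, data.frame(start = r1$query_start,
                                                     end = r1$query_end))))
  oracle <- seed_extend_align(mref, mq)
  # same reference footprint after trimming against round 1
  cover <- function(st, en) {
    if (!length(st)) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(st + 1L, en))
  }
  got <- cover(r2$ref_start, r2$ref_end)
  exp_cov <- cover(oracle$ref_start, oracle$ref_end)
  overlap <- sum(IRanges::width(IRanges::intersect(got, exp_cov)))
  expect_gte(overlap, 0.9 * sum(IRanges::width(exp_cov)))
  # masking invariant: round-2 never overlaps round-1 on the reference
  expect_equal(sum(IRanges::width(IRanges::intersect(
    cover(r1$ref_start, r1$ref_end), got))), 0)
})

test_that("no round-1 hits makes two rounds equal one round", {
  set.seed(5)
  ref <- list(sequences = c(r = random_dna(5000L)))
  query <- list(sequences = c(q = random_dna(5000L)))
  one <- seed_extend_align(ref, query)
  two <- two_round_align(ref, query)
  expect_equal(nrow(two), nrow(one))
  if (nrow(two)) expect_true(all(two$round == 1L))
})

test_that("a single block chains to itself with identical span", {
  b <- data.frame(ref_chrom = "r", ref_start = 10L, ref_end = 60L,
                  query_chrom = "q", query_start = 100L, query_end = 150L,
                  strand = "+", score = 50,
                  ref_aln = strrep("A", 50), query_aln = strrep("A", 50),
                  stringsAsFactors = FALSE)
  ch <- chain_blocks(b)
  expect_equal(unique(ch$chain_id), 1L)
  cs <- chain_summary(ch)
  expect_equal(cs$ref_start, 10L)
  expect_equal(cs$ref_end, 60L)
  expect_equal(cs$total_score, 50)
})

test_that("three collinear nearby blocks chain into one", {
  mk <- function(rs, qs, len = 200L, score = 200)
    data.frame(ref_chrom = "r", ref_start = rs, ref_end = rs + len,
               query_chrom = "q", query_start = qs, query_end = qs + len,
               strand = "+", score = score, ref_aln = strrep("A", len),
               query_aln = strrep("A", len), stringsAsFactors = FALSE)
  blocks <- rbind(mk(0L, 0L), mk(300L, 300L), mk(600L, 600L))
  ch <- chain_blocks(blocks, max_gap = 1000)
  expect_equal(length(unique(ch$chain_id)), 1L)
  # oracle: exhaustive chaining over all subsets
  expect_equal(chain_summary(ch)$total_score[1], brute_best_chain(blocks))
})

test_that("blocks on different query sequences never chain together", {
  mk <- function(qchrom) data.frame(
    ref_chrom = "r", ref_start = c(0L, 300L), ref_end = c(200L, 500L),
    query_chrom = qchrom, query_start = c(0L, 300L), query_end = c(200L, 500L),
    strand = "+", score = 200, ref_aln = strrep("A", 200),
    query_aln = strrep("A", 200), stringsAsFactors = FALSE)
  blocks <- rbind(mk("q1")[1, ], mk("q2")[2, ])
  ch <- chain_blocks(blocks)
  expect_equal(length(unique(ch$chain_id)), 2L)
})

test_that("chaining DP equals brute-force enumeration on random block sets", {
  set.seed(42)
  for (case in seq_len(50)) {
    n <- sample(2:8, 1)
    rs <- sort(sample.int(5000L, n))
    len <- sample(50:200, n, replace = TRUE)
    blocks <- data.frame(
      ref_chrom = "r", ref_start = rs, ref_end = rs + len,
      query_chrom = "q",
      query_start = qs <- sample.int(5000L, n), query_end = qs + len,
      strand = "+", score = sample(50:300, n, replace = TRUE),
      ref_aln = strrep("A", len), query_aln = strrep("A", len),
      stringsAsFactors = FALSE)
    ch <- chain_blocks(blocks, max_gap = 2000)
    expect_equal(max(chain_summary(ch)$total_score),
                 brute_best_chain(blocks, max_gap = 2000),
                 tolerance = 1e-9)
  }
})

test_that("netting keeps disjoint chains whole and resolves dominance", {
  mk <- function(rs, len, score, qs = rs)
    data.frame(ref_chrom = "r", ref_start = rs, ref_end = rs + len,
               query_chrom = "q", query_start = qs, query_end = qs + len,
               strand = "+", score = score, ref_aln = strrep("A", len),
               query_aln = strrep("A", len), stringsAsFactors = FALSE)
  # disjoint: both kept whole
  net <- net_chains(chain_blocks(rbind(mk(0L, 100L, 100), mk(500L, 100L, 90,
                                                             qs = 2000L))))
  expect_equal(nrow(net), 2L)
  # full overlap: only the higher-scoring survives
  full <- rbind(mk(0L, 100L, 100), mk(0L, 100L, 80, qs = 3000L))
  net <- net_chains(chain_blocks(full))
  expect_equal(nrow(net), 1L)
  expect_equal(net$query_start, 0L)
  # partial overlap: loser trimmed; kept coverage equals the union
  part <- rbind(mk(0L, 200L, 200), mk(100L, 200L, 150, qs = 4000L))
  net <- net_chains(chain_blocks(part))
  expect_equal(sum(net$ref_end - net$ref_start), 300L)
  ir <- IRanges::reduce(IRanges::IRanges(net$ref_start + 1L, net$ref_end))
  expect_equal(sum(IRanges::width(ir)), 300L)
})

test_that("gapped blocks trim consistently on both strands", {
  b <- data.frame(ref_chrom = "r", ref_start = 100L, ref_end = 110L,
                  query_chrom = "q", query_start = 50L, query_end = 58L,
                  strand = "+", score = 0,
                  ref_aln = "ACGTACGTAC", query_aln = "AC--ACGTAC",
                  stringsAsFactors = FALSE)
  t1 <- trim_block_ref_range(b, 104L, 110L)
  expect_equal(t1$ref_aln, "ACGTAC")
  expect_equal(t1$query_start, 52L)
  expect_equal(t1$query_end, 58L)
  bm <- b; bm$strand <- "-"
  t2 <- trim_block_ref_range(bm, 104L, 110L)
  # on the minus strand the right end of the alignment is the query start
  expect_equal(t2$query_start, 50L)
  expect_equal(t2$query_end, 56L)
})
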