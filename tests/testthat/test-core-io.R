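test_that("FASTA writing and reading round-trips names and sequences", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(alpha = "ACGTNacgt", beta = "TTTTGGGGCCCCAAAA")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(back, seqs)
})

test_that("a 1 Mb record round-trips byte-identically", {
  f <- withr::local_tempfile(fileext = ".fa")
  set.seed(11)
  big <- c(chrBig = random_dna(1000000L))
  write_fasta(big, f)
  expect_identical(read_fasta(f), big)
})

test_that("degenerate FASTA input is rejected", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">empty", "", ">next", "ACGT"), f)
  expect_error(read_fasta(f), "empty sequence")
  writeLines(c("ACGT", ">late", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
  expect_error(write_fasta(c(x = ""), withr::local_tempfile()), "empty")
})

test_that("BED parses 0-based half-open verbatim and round-trips", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", f)
  df <- read_bed(f)
  expect_equal(df[, c("chrom", "start", "end")],
               data.frame(chrom = "chr1", start = 10L, end = 20L))
  set.seed(3)
  n <- 100L
  ivs <- interval_df(chrom = sample(c("c1", "c2"), n, TRUE),
                     start = s <- sample.int(10000L, n),
                     end = s + sample.int(500L, n),
                     strand = sample(c("+", "-"), n, TRUE))
  ivs$name <- sprintf("iv%03d", seq_len(n))
  write_bed(ivs, f)
  back <- read_bed(f)
  key <- function(d) sort(paste(d$chrom, d$start, d$end, d$strand, d$name))
  expect_identical(key(back), key(ivs))
})

test_that("BED rows with start >= end are dropped with a warning log", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t5\t5", "chr1\t10\t20"), f)
  withr::local_options(cnevol.log_level = "warn")
  expect_message(df <- read_bed(f), "dropped 1")
  expect_equal(nrow(df), 1L)
})

test_that("GFF3 exons convert from 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t11\t20\t.\t+\t.\tID=e1;Parent=g1",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1"), f)
  ex <- read_gff3_exons(f)
  expect_equal(ex$start, 10L)
  expect_equal(ex$end, 20L)
  expect_equal(ex$parent, "g1")
  genes <- read_gff3_exons(f, feature = "gene")
  expect_equal(genes$id, "g1")
})

test_that("gene annotations written as GFF3 read back consistently", {
  f <- withr::local_tempfile(fileext = ".gff3")
  genes <- data.frame(chrom = "chr2", start = 100L, end = 500L, strand = "-",
                      gene_id = "gX")
  exons <- data.frame(chrom = "chr2", start = c(100L, 300L),
                      end = c(200L, 500L), strand = "-", gene_id = "gX")
  write_gff3(genes, exons, f)
  expect_equal(read_gff3_exons(f, "gene")[, c("start", "end")],
               data.frame(start = 100L, end = 500L))
  expect_equal(read_gff3_exons(f)$start, c(100L, 300L))
})

test_that("AXT blocks round-trip, including gapped rows", {
  f <- withr::local_tempfile(fileext = ".axt")
  blocks <- data.frame(
    ref_chrom = "chr1", ref_start = 100L, ref_end = 150L,
    query_chrom = "q1", query_start = 40L, query_end = 90L, strand = "+",
    score = 50, ref_aln = strrep("A", 50), query_aln = strrep("A", 50),
    stringsAsFactors = FALSE)
  write_axt(blocks, f)
  back <- read_axt(f)
  expect_equal(back[names(blocks)], blocks)
  gapped <- blocks
  gapped$ref_aln <- paste0(strrep("A", 20), "--", strrep("A", 30))
  gapped$query_aln <- paste0(strrep("A", 18), "----", strrep("A", 30))
  gapped$ref_end <- 150L; gapped$query_end <- 88L
  write_axt(gapped, f)
  back <- read_axt(f)
  expect_equal(nchar(back$ref_aln), nchar(back$query_aln))
  expect_equal(back$query_end - back$query_start,
               nchar(gsub("-", "", back$query_aln)))
})

test_that("minus-strand AXT coordinates map back through the forward strand", {
  qlen <- c(q1 = 1000L)
  qseq <- random_dna(1000L)
  # a minus-strand block: ref segment aligns the revcomp of query[300, 360)
  ref_seg <- revcomp(substr(qseq, 301, 360))
  blocks <- data.frame(
    ref_chrom = "chr1", ref_start = 10L, ref_end = 70L,
    query_chrom = "q1", query_start = 300L, query_end = 360L, strand = "-",
    score = 60, ref_aln = ref_seg, query_aln = ref_seg,
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".axt")
  write_axt(blocks, f, query_seqlens = qlen)
  # AXT stores reverse-complemented query coordinates on minus blocks
  hdr <- strsplit(readLines(f)[1], " ")[[1]]
  expect_equal(as.integer(hdr[6]), 1000L - 360L + 1L)
  expect_equal(as.integer(hdr[7]), 1000L - 300L)
  back <- read_axt(f, query_seqlens = qlen)
  expect_equal(back$query_start, 300L)
  expect_equal(back$query_end, 360L)
  # coordinate algebra oracle: re-extract and revcomp-compare the sequence
  expect_identical(revcomp(substr(qseq, back$query_start + 1L, back$query_end)),
                   gsub("-", "", back$query_aln))
  expect_error(read_axt(f), "query_seqlens")
})

test_that("orthology tables round-trip and enforce uniqueness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(species_id = c("s1", "s1"), gene_id = c("g1", "g2"),
                   orthogroup_id = c("OG1", "OG1"),
                   paralog_partner_ids = c("g2", "g1"),
                   paralog_origin = c("pre-WGD", "pre-WGD"),
                   stringsAsFactors = FALSE)
  write_orthology(df, f)
  expect_equal(read_orthology(f), df)
  bad <- df; bad$gene_id <- "g1"
  write_orthology(bad, f)
  expect_error(read_orthology(f), "duplicated")
})

test_that("interval validation and species tree invariants hold", {
  expect_error(interval_df("chr1", 5, 5), "start < end")
  expect_error(interval_df("", 1, 5), "empty chrom")
  phy <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_error(species_tree(phy, c("a", "b"), c("b", "c")), "disjoint")
  expect_error(species_tree(phy, "a", c("c", "z")), "not tree leaves")
  st <- species_tree(phy, c("a", "b"), c("c", "d"))
  expect_s3_class(st, "species_tree")
})

test_that("genome_set maps foreign characters to N and indexes N runs as repeats", {
  gs <- suppressWarnings(genome_set(list(
    sp1 = list(sequences = c(chr1 = "ACGTXXACGTNNNNACGT")))))
  expect_match(gs$sp1$sequences[["chr1"]], "^ACGTNNACGTNNNNACGT$")
  # both the mapped run and the hard-masked run appear as repeats
  expect_true(nrow(gs$sp1$repeats) >= 2)
  expect_error(genome_set(list(s = list(
    sequences = c(chr1 = "ACGT"),
    exons = interval_df("chr1", 2, 10)))), "outside")
})
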