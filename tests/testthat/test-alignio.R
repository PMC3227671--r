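test_that("gapped_pair validates its invariants", {
  p <- gapped_pair("AC-GT", "ACTG-")
  expect_equal(nchar(p$text_a), nchar(p$text_b))
  expect_equal(p$loc_a$end, 4L)
  expect_equal(p$loc_b$end, 4L)
  expect_error(gapped_pair("ACGT", "ACG"), "equal")
  expect_error(gapped_pair("A-GT", "A-GT"), "both")
  expect_error(gapped_pair("AXGT", "ACGT"), "invalid character")
  # lowercase is uppercased
  expect_equal(gapped_pair("acgt", "acgt")$text_a, "ACGT")
})

test_that("AXT identity block parses with converted coordinates", {
  axt <- c("0 chr1 1 10 chrA 1 10 + 100", "ACGTACGTAC", "ACGTACGTAC", "")
  tf <- tempfile(); writeLines(axt, tf)
  got <- read_axt(tf)
  expect_length(got, 1L)
  p <- got[[1]]
  expect_equal(p$loc_a$chrom, "chr1")
  expect_equal(p$loc_a$start, 0L)
  expect_equal(p$loc_a$end, 10L)
  expect_equal(p$loc_a$strand, "+")
  expect_identical(p$text_a, p$text_b)
})

test_that("AXT single-gap bookkeeping and malformed blocks", {
  axt <- c("0 chr1 1 10 chrA 1 9 + 100", "ACGTACGTAC", "ACGT-CGTAC", "")
  tf <- tempfile(); writeLines(axt, tf)
  p <- read_axt(tf)[[1]]
  expect_equal(p$loc_b$end - p$loc_b$start, nchar(p$text_b) - 1L)
  bad <- c("0 chr1 1 10 chrA 1 10 + 100", "ACGTACGTAC", "ACGTAC", "")
  writeLines(bad, tf)
  expect_error(read_axt(tf), "block 1")
  bad2 <- c("0 chr1 1 10 chrA 1 8 + 100", "ACGTACGTAC", "ACGT-CGTAC", "")
  writeLines(bad2, tf)
  expect_error(read_axt(tf), "span")
})

test_that("AXT read -> write -> read round-trips on random fixtures", {
  set.seed(11)
  pairs <- replicate(5, random_gapped_pair(80), simplify = FALSE)
  tf <- tempfile()
  write_axt(pairs, tf)
  back <- read_axt(tf)
  expect_length(back, 5L)
  for (i in seq_along(pairs)) {
    expect_equal(back[[i]]$text_a, pairs[[i]]$text_a)
    expect_equal(back[[i]]$text_b, pairs[[i]]$text_b)
    expect_equal(back[[i]]$loc_a$start, pairs[[i]]$loc_a$start)
    expect_equal(back[[i]]$loc_b$end, pairs[[i]]$loc_b$end)
  }
})

test_that("MAF blocks become pairs or multiple alignments", {
  maf <- c("##maf version=1", "a score=1.0",
           "s hg.chr1 10 5 + 1000 ACG-TA",
           "s pt.chr2  3 6 - 2000 ACGCTA",
           "", "a score=2.0",
           "s hg.chr1 0 4 + 1000 ACGT",
           "s pt.chr1 0 4 + 2000 ACGT",
           "s gg.chr1 0 4 + 3000 ACGT",
           "s pa.chr1 0 4 + 4000 ACTT")
  tf <- tempfile(); writeLines(maf, tf)
  got <- read_maf(tf)
  expect_length(got, 2L)
  expect_s3_class(got[[1]], "gapped_pair")
  expect_equal(got[[1]]$loc_b$strand, "-")
  expect_equal(attr(got[[1]], "src_sizes")[["pt.chr2"]], 2000L)
  expect_s3_class(got[[2]], "multiple_alignment")
  expect_length(got[[2]]$rows, 4L)
  bad <- c("a", "s x 0 4 + 10 ACGT", "s y 0 3 + 10 ACG")
  writeLines(bad, tf)
  expect_error(read_maf(tf), "lengths differ")
})

test_that("pair FASTA round-trips, uppercases, and rejects bad input", {
  set.seed(12)
  p <- random_gapped_pair(50)
  tf <- tempfile()
  write_pair_fasta(p, tf)
  back <- read_pair_fasta(tf)
  expect_equal(back$text_a, p$text_a)
  expect_equal(back$text_b, p$text_b)
  writeLines(c(">a", "acg-t", ">b", "acgct"), tf)
  expect_equal(read_pair_fasta(tf)$text_a, "ACG-T")
  writeLines(c(">a", "ACGT"), tf)
  expect_error(read_pair_fasta(tf), "2 FASTA")
  writeLines(c(">a", "ACGT", ">b", "ACG"), tf)
  expect_error(read_pair_fasta(tf), "unequal")
  writeLines(c(">a", "ACXT", ">b", "ACGT"), tf)
  expect_error(read_pair_fasta(tf), "invalid")
})

test_that("BED reading: basics, empty file, sorting on demand", {
  tf <- tempfile()
  writeLines("chr1\t5\t10", tf)
  b <- read_bed(tf)
  expect_equal(b$start, 5L)
  expect_equal(b$end, 10L)
  expect_equal(b$strand, "+")
  writeLines(character(0), tf)
  expect_equal(nrow(read_bed(tf)), 0L)
  writeLines(c("chr2\t100\t200", "chr1\t50\t60", "chr1\t5\t10"), tf)
  srt <- read_bed(tf, sort = TRUE)
  expect_equal(srt$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(srt$start, c(5L, 50L, 100L))
  writeLines("chr1\t10\t5", tf)
  expect_error(read_bed(tf), "malformed")
})

test_that("column/genome maps agree with a naive per-column walk", {
  set.seed(13)
  for (rep in 1:5) {
    p <- random_gapped_pair(70)
    ca <- strsplit(p$text_a, "")[[1]]
    # naive walk oracle
    pos <- -1L
    for (col in seq_along(ca)) {
      if (ca[col] != "-") {
        pos <- pos + 1L
        expect_equal(column_to_genome(p, col - 1L, "a"), pos)
        expect_equal(genome_to_column(p, pos, "a"), col - 1L)
      } else {
        expect_true(is.na(column_to_genome(p, col - 1L, "a")))
      }
    }
  }
  p <- gapped_pair("ACGT", "ACGT")
  expect_equal(column_to_genome(p, 3L, "a"), p$loc_a$start + 3L)
  expect_error(column_to_genome(p, 4L, "a"), "range")
})

test_that("inversion TSV writes sorted, round-trips, handles empty sets", {
  tf <- tempfile()
  write_inversion_tsv(NULL, tf)
  expect_equal(nrow(read_inversion_tsv(tf)), 0L)
  calls <- data.frame(
    id = c("x.1", "x.2"), chrom_a = "chr1", start_a = c(500L, 100L),
    end_a = c(510L, 110L), chrom_b = "chrB", start_b = c(50L, 10L),
    end_b = c(60L, 20L), length_bp = 10L, criterion = c("i", "ii"),
    similarity_inverted = c(1, 0.97), similarity_forward = c(0.4, 0.2),
    at_exclusive = c(FALSE, TRUE), lineage = c(NA, "chimpanzee"),
    seg_a = "ACGTACGTAC", seg_b = "GTACGTACGT", stringsAsFactors = FALSE)
  write_inversion_tsv(calls, tf)
  back <- read_inversion_tsv(tf)
  expect_equal(back$start_a, c(100L, 500L))  # sorted
  expect_equal(back$criterion, c("ii", "i"))
  expect_equal(back$at_exclusive, c(TRUE, FALSE))
  expect_equal(back$lineage, c("chimpanzee", NA))
  expect_equal(back$similarity_inverted, c(0.97, 1))
})

test_that("ungapped text length always matches the interval width", {
  set.seed(14)
  for (rep in 1:10) {
    p <- random_gapped_pair(40)
    expect_equal(nchar(gsub("-", "", p$text_a)),
                 p$loc_a$end - p$loc_a$start)
    expect_equal(nchar(gsub("-", "", p$text_b)),
                 p$loc_b$end - p$loc_b$start)
  }
})
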