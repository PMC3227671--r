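test_that("score_simulation: perfect and empty detectors", {
  truths <- data.frame(pair = c("p1", "p2"), start = c(10L, 20L),
                       end = c(20L, 40L), length = c(10L, 20L))
  calls <- data.frame(pair = c("p1", "p2"), start_b = c(10L, 20L),
                      end_b = c(20L, 40L), length_bp = c(10L, 20L))
  r <- score_simulation(calls, truths)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$false_positives, 0L)
  expect_equal(r$ppv, 1.0)
  r0 <- score_simulation(NULL, truths)
  expect_equal(r0$sensitivity, 0.0)
  expect_equal(r0$true_positives + r0$false_negatives, 2L)
  expect_false(attr(r0, "ppv_defined"))
})

test_that("scoring agrees with a brute-force overlap oracle", {
  set.seed(81)
  for (rep in 1:10) {
    n_t <- 15; n_c <- 25
    truths <- data.frame(pair = sample(paste0("p", 1:5), n_t, TRUE),
                         start = sample(0:500, n_t))
    truths$end <- truths$start + sample(5:50, n_t, TRUE)
    truths$length <- truths$end - truths$start
    calls <- data.frame(pair = sample(paste0("p", 1:5), n_c, TRUE),
                        start_b = sample(0:500, n_c))
    calls$end_b <- calls$start_b + sample(5:50, n_c, TRUE)
    calls$length_bp <- calls$end_b - calls$start_b
    r <- score_simulation(calls, truths)
    # oracle: all-pairs overlap with the 50 bp margin
    tp <- 0
    call_used <- rep(FALSE, n_c)
    for (i in seq_len(n_t)) {
      hit <- FALSE
      for (j in seq_len(n_c)) {
        if (calls$pair[j] == truths$pair[i] &&
            calls$start_b[j] < truths$end[i] + 50 &&
            truths$start[i] - 50 < calls$end_b[j]) {
          hit <- TRUE; call_used[j] <- TRUE
        }
      }
      tp <- tp + hit
    }
    expect_equal(r$true_positives, tp)
    expect_equal(r$false_positives, sum(!call_used))
    expect_equal(r$true_positives + r$false_negatives, n_t)
  }
})

test_that("strict match rule enforces the +/-50% length window", {
  expect_true(length_bounded_match_rule(10, 20, 10, 12, 22, 10))
  expect_false(length_bounded_match_rule(10, 14, 4, 12, 22, 10))
  expect_false(length_bounded_match_rule(10, 26, 16, 12, 22, 10))
  expect_false(length_bounded_match_rule(100, 110, 10, 12, 22, 10))
})

test_that("calls on feature boundaries all land in distance bin zero", {
  set.seed(82)
  features <- data.frame(chrom = "chr1", start = c(100L, 400L),
                         end = c(200L, 500L))
  calls <- data.frame(chrom = "chr1", start = c(95L, 395L),
                      end = c(105L, 405L))
  res <- feature_proximity_test(calls, features, c(chr1 = 1000L),
                                n_trials = 50)
  expect_equal(res$observed[1], 2L)
  expect_equal(sum(res$observed), nrow(calls))
  expect_error(feature_proximity_test(calls, features[0, ],
                                      c(chr1 = 1000L)), "empty")
})

test_that("proximity p-values are calibrated under a uniform null", {
  set.seed(83)
  features <- data.frame(chrom = "chr1",
                         start = seq(0L, 90000L, by = 2000L))
  features$end <- features$start + 500L
  calls <- data.frame(chrom = "chr1", start = sample(0:99000, 40))
  calls$end <- calls$start + 20L
  res <- feature_proximity_test(calls, features, c(chr1 = 100000L),
                                n_trials = 999)
  # uniform calls are not enriched anywhere near p < 0.001
  expect_gt(min(res$p), 0.001)
  expect_true(all(res$p >= 1 / 1000 & res$p <= 1))
  expect_equal(sum(res$observed), nrow(calls))
})

test_that("inverted-repeat flanks: construction, windows, p-values", {
  set.seed(84)
  left_rep <- "ACGGATTACCGT"  # 12 bp
  chrom <- paste0(random_dna(100), left_rep, random_dna(15),
                  rc_oracle(left_rep), random_dna(100))
  # inversion spans the 15 bp between the repeats
  calls <- data.frame(chrom = "c1", start = 112L, end = 127L)
  seqs <- list(c1 = chrom)
  res <- inverted_repeat_flank_test(calls, seqs, min_repeat = 10L,
                                    window = 30L, n_trials = 99)
  expect_equal(res$n_flagged, 1L)
  expect_true(res$p_value >= 1 / 100 && res$p_value <= 1)
  # min_repeat larger than the window can never flag
  res2 <- inverted_repeat_flank_test(calls, seqs, min_repeat = 40L,
                                     window = 30L, n_trials = 19)
  expect_equal(res2$n_flagged, 0L)
})

test_that("divergence: examples, exclusion, degenerate input", {
  expect_equal(divergence(gapped_pair("ACGT", "ACGT")), 0)
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 50), "C", strrep("A", 49))
  expect_equal(divergence(gapped_pair(a, b)), 0.01)
  excl <- data.frame(chrom_a = "pair", start_a = 45L, end_a = 55L)
  expect_equal(divergence(gapped_pair(a, b), exclude = excl), 0)
  expect_equal(divergence(gapped_pair("-AA", "AA-")), 0)
  expect_error(divergence(gapped_pair("-A", "A-")), "zero aligned")
})

test_that("per-chromosome densities conserve totals and handle empties", {
  set.seed(85)
  sizes <- c(chr1 = 2e6, chr2 = 1e6)
  calls <- data.frame(chrom = c(rep("chr1", 6), rep("chr2", 3)),
                      start = 1000L * (1:9))
  calls$end <- calls$start + 10L
  d <- density_by_chrom(calls, sizes, n_boot = 200, n_trials = 200)
  expect_equal(sum(d$n), nrow(calls))
  expect_equal(d$density, d$n / (sizes / 1e6), ignore_attr = TRUE)
  expect_true(all(d$p_enriched >= 1 / 201))
  d0 <- density_by_chrom(calls[0, ], sizes, n_boot = 10, n_trials = 10)
  expect_equal(d0$n, c(0L, 0L))
  expect_equal(d0$density, c(0, 0))
  bad <- data.frame(chrom = "chrX", start = 1L, end = 2L)
  expect_error(density_by_chrom(bad, sizes), "unknown")
})

test_that("uniform calls show no chromosome-level enrichment", {
  set.seed(86)
  sizes <- c(chr1 = 3e6, chr2 = 2e6, chr3 = 1e6)
  n <- 120
  ch <- sample(names(sizes), n, TRUE, prob = sizes / sum(sizes))
  calls <- data.frame(chrom = ch, start = 100L * (1:n))
  calls$end <- calls$start + 10L
  d <- density_by_chrom(calls, sizes, n_boot = 100, n_trials = 500)
  expect_gt(min(d$p_enriched), 0.002)
  expect_gt(min(d$p_depleted), 0.002)
})
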