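test_that("reverse_complement: involution, examples, invalid input", {
  expect_equal(reverse_complement("ACGT"), "ACGT")  # palindrome
  expect_equal(reverse_complement("AAAT"), "ATTT")
  expect_error(reverse_complement("ACGU"), "invalid")
  set.seed(31)
  for (rep in 1:20) {
    s <- random_dna(sample(5:40, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), rc_oracle(s))
  }
})

test_that("similarity counts identical columns; gaps and N never match", {
  expect_equal(similarity("ACGT", "ACGT"), 1.0)
  expect_equal(similarity("ACGT", "ACGA"), 0.75)
  expect_equal(similarity("AC-T", "ACGT"), 0.75)
  expect_equal(similarity("ANGT", "ANGT"), 0.75)
  expect_error(similarity("ACG", "ACGT"), "equal")
})

test_that("seeded search finds a full-length identity hit", {
  s <- "ACGTTGCAACGGATTACCAG"
  hits <- seed_extend_search(s, s)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$q_start[1], 0L)
  expect_equal(hits$q_end[1], 20L)
  expect_equal(hits$t_start[1], 0L)
  expect_equal(hits$t_end[1], 20L)
  expect_equal(hits$similarity[1], 1.0)
  expect_equal(hits$score[1], 20L)
})

test_that("no shared word gives no hits", {
  # disjoint alphabets at the 5-mer level
  expect_equal(nrow(seed_extend_search(strrep("AC", 10), strrep("GT", 10))),
               0L)
})

test_that("top seeded hit matches exhaustive local alignment on <=30 bp", {
  set.seed(32)
  checked <- 0
  for (rep in 1:60) {
    core <- random_dna(sample(8:14, 1))
    q <- paste0(random_dna(sample(0:8, 1)), core, random_dna(sample(0:8, 1)))
    t_ <- paste0(random_dna(sample(0:8, 1)), core, random_dna(sample(0:8, 1)))
    # sprinkle a mutation into the target copy sometimes
    if (runif(1) < 0.5) {
      i <- sample(nchar(t_), 1)
      substr(t_, i, i) <- sample(c("A", "C", "G", "T"), 1)
    }
    hits <- seed_extend_search(q, t_)
    if (nrow(hits) == 0L) next
    checked <- checked + 1
    expect_equal(hits$score[1], sw_oracle(q, t_))
  }
  expect_gte(checked, 40)
})

test_that("hit expectation values follow the Karlin-Altschul formula", {
  cfg <- detector_config()
  s <- "ACGTTGCAACGGATTACCAG"
  hits <- seed_extend_search(s, s, cfg)
  expect_equal(hits$evalue[1],
               cfg$ka_k * 20 * 20 * exp(-cfg$ka_lambda * 20))
})

test_that("a planted non-palindromic inversion yields a criterion-i call", {
  set.seed(33)
  fx <- planted_fixture(segments = list("ACGTTGACAC"))
  calls <- scan_pair(fx$pair, rate_params(0.01, 0.0015))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$criterion, "i")
  expect_equal(calls$length_bp, 10L)
  expect_equal(calls$similarity_inverted, 1.0)
  expect_equal(calls$start_b, fx$truth$start)
  expect_equal(calls$end_b, fx$truth$end)
  # the call explains the region: reverse-complementing the called segment
  # restores the original sequence
  seg <- substr(fx$seq_b, calls$start_b + 1, calls$end_b)
  expect_equal(reverse_complement(seg),
               substr(fx$seq_a, calls$start_a + 1, calls$end_a))
})

test_that("a perfectly palindromic segment is invisible", {
  set.seed(34)
  # palindrome: identical forward, no difference events, no call
  fx <- planted_fixture(segments = list("ACGCGCGT"))
  expect_equal(reverse_complement("ACGCGCGT"), "ACGCGCGT")
  calls <- scan_pair(fx$pair, rate_params(0.01, 0.0015))
  expect_equal(nrow(calls), 0L)
})

test_that("near-palindromic segments fail the similarity-ratio test", {
  set.seed(35)
  # a palindrome with 3 scattered substitutions: forward and inverted
  # similarities are comparable, so >1.25x cannot hold
  x <- random_dna(12)
  p24 <- paste0(x, rc_oracle(x))
  s <- p24
  for (i in c(3, 11, 19)) substr(s, i, i) <- "A"
  flanks <- random_dna(150)
  seq_a <- paste0(flanks, p24, random_dna(150))
  seq_b <- sub(p24, s, seq_a, fixed = TRUE)
  pair <- global_affine_align(seq_a, seq_b)
  calls <- scan_pair(pair, rate_params(0.01, 0.0015))
  expect_equal(nrow(calls), 0L)
})

# Hand-built partially palindromic alignment: segment s = palindromic core
# with a tail; its inverted copy aligns as two staggered gap blocks on
# different rows sandwiching the identical core.
staggered_pair <- function(core, tail, left, right, mutate_core_at = NA) {
  s <- paste0(core, tail)                    # segment in species A
  rc_tail <- rc_oracle(tail)
  core_b <- core
  if (!is.na(mutate_core_at)) {
    old <- substr(core_b, mutate_core_at, mutate_core_at)
    substr(core_b, mutate_core_at, mutate_core_at) <-
      setdiff(c("A", "C", "G", "T"), old)[1]
  }
  k <- nchar(tail)
  text_a <- paste0(left, strrep("-", k), core, tail, right)
  text_b <- paste0(left, rc_tail, core_b, strrep("-", k), right)
  gapped_pair(text_a, text_b)
}

test_that("partially palindromic inversions are called under criterion ii", {
  set.seed(36)
  left <- random_dna(150); right <- random_dna(150)
  pair <- staggered_pair("ACGCGT", "AA", left, right)
  calls <- scan_pair(pair, rate_params(0.01, 0.0015))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$criterion, "ii")
  expect_equal(calls$length_bp, 8L)
  expect_equal(calls$similarity_inverted, 1.0)
})

test_that("duo candidates fail when the sandwiched run is half or less", {
  set.seed(37)
  # 4 bp palindromic core inside a 12 bp segment: 4/12 < 50%
  left <- random_dna(150); right <- random_dna(150)
  pair <- staggered_pair("ACGT", "AAAACCGG", left, right)
  calls <- scan_pair(pair, rate_params(0.01, 0.0015))
  expect_equal(nrow(calls[calls$criterion == "ii", ]), 0L)
})

test_that("criterion ii demands perfect inverted similarity", {
  set.seed(38)
  left <- random_dna(150); right <- random_dna(150)
  # break the inverted identity inside the sandwiched core
  pair <- staggered_pair("ACGCGT", "AA", left, right, mutate_core_at = 3)
  calls <- scan_pair(pair, rate_params(0.01, 0.0015))
  expect_equal(nrow(calls[calls$criterion == "ii", ]), 0L)
})

test_that("AT repeat filter matches the canonical patterns", {
  expect_true(at_repeat_filter("AAATTTTTTT", "AAAAAAATTT"))
  expect_true(at_repeat_filter("ATATATATATA", "TATATATATAT"))
  expect_false(at_repeat_filter("AATTTAT", "ATAAATT"))
  expect_true(at_repeat_filter("TTTAA", "TTAAA"))       # T-then-A runs
  expect_true(at_repeat_filter("AAAAA", "TTTTT"))       # pure runs
  expect_false(at_repeat_filter("ACGT", "ACGT"))        # not AT-only
  expect_false(at_repeat_filter("ATTAATTA", "TAATTAAT"))  # mixed blocks
})

test_that("AT-exclusive classification checks both segments", {
  expect_true(classify_at_exclusive("ATTA", "TAAT"))
  expect_false(classify_at_exclusive("ATGA", "TCAT"))
  set.seed(39)
  for (rep in 1:10) {
    s <- random_dna(12, comp = c(A = 0.5, C = 0, G = 0, T = 0.5))
    expect_true(classify_at_exclusive(s, rc_oracle(s)))
  }
})

test_that("scan_pair: identity input, two inversions, determinism", {
  expect_equal(nrow(scan_pair(gapped_pair(strrep("ACGT", 50),
                                          strrep("ACGT", 50)),
                              rate_params(0.01, 0.0015))), 0L)
  set.seed(40)
  fx <- planted_fixture(segments = list("ACGTTGACAC", "TTGACCTGGATCAGT"),
                        gap_between = 200)
  calls <- scan_pair(fx$pair, rate_params(0.01, 0.0015))
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$start_b, fx$truth$start)
  expect_equal(calls$end_b, fx$truth$end)
  calls2 <- scan_pair(fx$pair, rate_params(0.01, 0.0015))
  expect_identical(calls, calls2)
})

test_that("scan_pair is row-symmetric up to coordinate transposition", {
  set.seed(41)
  fx <- planted_fixture(segments = list("ACGTTGACAC"))
  swapped <- gapped_pair(fx$pair$text_b, fx$pair$text_a, id = fx$pair$id)
  c1 <- scan_pair(fx$pair, rate_params(0.01, 0.0015))
  c2 <- scan_pair(swapped, rate_params(0.01, 0.0015))
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(c1$start_a, c2$start_b)
  expect_equal(c1$end_a, c2$end_b)
  expect_equal(c1$start_b, c2$start_a)
  expect_equal(c1$seg_a, c2$seg_b)
})

test_that("emitted calls explain their regions on simulated pairs", {
  set.seed(42)
  r <- run_sensitivity_study(15, 25, root_length = 600, seed = 4242,
                             keep_sets = TRUE)
  calls <- r$calls
  expect_gt(nrow(calls), 5)
  seqs <- setNames(lapply(r$sets, function(s) s$sim),
                   vapply(r$sets, function(s) s$pair$id, ""))
  for (i in seq_len(nrow(calls))) {
    sim <- seqs[[calls$pair[i]]]
    # substituting the reverse complement of the called B segment must
    # reconcile the two sequences locally: the replaced B equals A over
    # the called A interval
    seg_b <- substr(sim$seq_b, calls$start_b[i] + 1, calls$end_b[i])
    seg_a <- substr(sim$seq_a, calls$start_a[i] + 1, calls$end_a[i])
    sim_inv <- similarity(reverse_complement(seg_b), seg_a)
    sim_fwd <- calls$similarity_forward[i]
    expect_gte(sim_inv, calls$similarity_inverted[i] - 1e-9)
    expect_gt(sim_inv, sim_fwd)
  }
})
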