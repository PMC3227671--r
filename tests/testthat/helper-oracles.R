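# Independent reference implementations used as test oracles.  These are
# deliberately naive (loops, full matrices, enumeration) and share no code
# with the package internals they check.

random_dna <- function(n, comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

rc_oracle <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Full Smith-Waterman with affine gaps (three-state), best local score.
sw_oracle <- function(q, t, match = 1, mismatch = -3, gap_open = 5,
                      gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      s <- if (qc[i - 1] == tc[j - 1] && qc[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exhaustive enumeration of all global alignments of two short strings,
# scoring each with affine gap costs; returns the optimal score.
enum_global_oracle <- function(s1, s2, match = 2, mismatch = -3,
                               gap_open = 16, gap_extend = 1) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(c1) && j > length(c2)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(c1) && j <= length(c2)) {
      s <- if (c1[i] == c2[j] && c1[i] != "N") match else mismatch
      rec(i + 1, j + 1, score + s, "d")
    }
    if (i <= length(c1))  # gap in s2
      rec(i + 1, j, score - gap_extend -
            if (state == "g2") 0 else gap_open, "g2")
    if (j <= length(c2))  # gap in s1
      rec(i, j + 1, score - gap_extend -
            if (state == "g1") 0 else gap_open, "g1")
  }
  rec(1L, 1L, 0, "d")
  best
}

# Independent enumeration of qualifying trio/duo windows and interval
# merging, used against find_candidate_regions.
brute_candidates <- function(pair, p_d, p_g, alpha = 0.05,
                             extension = 50L) {
  ev <- find_difference_events(pair)  # event finding tested separately
  L <- nchar(pair$text_a)
  wins <- list()
  ne <- nrow(ev)
  if (ne >= 3) for (i in 1:(ne - 2)) {
    k <- ev$kind[i:(i + 2)]; gr <- ev$gap_row[i:(i + 2)]
    ng <- sum(k == "gap_block")
    ok <- (ng == 0) || (ng == 1) ||
      (ng == 2 && length(unique(gr[k == "gap_block"])) == 2)
    if (!ok) next
    n <- ev$col_end[i + 2] - ev$col_start[i]
    p <- 1 - (1 - p_d)^(n - 1) - (n - 1) * p_d * (1 - p_d)^(n - 2)
    if (p < alpha)
      wins[[length(wins) + 1]] <- c(ev$col_start[i], ev$col_end[i + 2], 1)
  }
  if (ne >= 2) for (i in 1:(ne - 1)) {
    if (ev$kind[i] == "gap_block" && ev$kind[i + 1] == "gap_block" &&
        ev$gap_row[i] != ev$gap_row[i + 1]) {
      n <- ev$col_end[i + 1] - ev$col_start[i]
      if (1 - (1 - p_g)^(n - 1) < alpha)
        wins[[length(wins) + 1]] <- c(ev$col_start[i], ev$col_end[i + 1], 2)
    }
  }
  merge_union <- function(ivs) {
    if (length(ivs) == 0) return(matrix(numeric(0), ncol = 2))
    m <- do.call(rbind, ivs)
    m <- m[order(m[, 1]), , drop = FALSE]
    out <- m[1, , drop = FALSE]
    if (nrow(m) > 1) for (r in 2:nrow(m)) {
      if (m[r, 1] < out[nrow(out), 2])
        out[nrow(out), 2] <- max(out[nrow(out), 2], m[r, 2])
      else out <- rbind(out, m[r, ])
    }
    out
  }
  res <- list()
  for (kind in 1:2) {
    sel <- Filter(function(w) w[3] == kind, wins)
    m <- merge_union(lapply(sel, function(w) w[1:2]))
    if (nrow(m) > 0) {
      m[, 1] <- pmax(0, m[, 1] - extension)
      m[, 2] <- pmin(L, m[, 2] + extension)
      m <- merge_union(lapply(seq_len(nrow(m)), function(r) m[r, ]))
    }
    res[[c("trio", "duo")[kind]]] <- m
  }
  res
}

# Random gapped pair built column by column (never '-' over '-').
random_gapped_pair <- function(n_cols = 60, gap_p = 0.1, mm_p = 0.1) {
  a <- character(n_cols); b <- character(n_cols)
  for (i in seq_len(n_cols)) {
    r <- runif(1)
    base <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    if (r < gap_p / 2) { a[i] <- "-"; b[i] <- base[1] }
    else if (r < gap_p) { a[i] <- base[1]; b[i] <- "-" }
    else if (r < gap_p + mm_p) {
      a[i] <- base[1]
      b[i] <- sample(setdiff(c("A", "C", "G", "T"), base[1]), 1)
    } else a[i] <- b[i] <- base[1]
  }
  gapped_pair(paste(a, collapse = ""), paste(b, collapse = ""))
}

# A pair with inversions planted in seq_b, realigned with the internal
# aligner; returns the pair plus truth intervals (seq_b coordinates).
planted_fixture <- function(flank = 150, segments = list("ACGTACGTAC"),
                            gap_between = 200,
                            comp = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25)) {
  parts_a <- character(0); parts_b <- character(0)
  truth <- NULL
  pos <- 0
  left <- random_dna(flank, comp)
  parts_a <- left; parts_b <- left; pos <- flank
  for (k in seq_along(segments)) {
    s <- segments[[k]]
    parts_a <- paste0(parts_a, s)
    parts_b <- paste0(parts_b, rc_oracle(s))
    truth <- rbind(truth, data.frame(start = pos, end = pos + nchar(s)))
    pos <- pos + nchar(s)
    mid <- random_dna(if (k < length(segments)) gap_between else flank,
                      comp)
    parts_a <- paste0(parts_a, mid); parts_b <- paste0(parts_b, mid)
    pos <- pos + nchar(mid)
  }
  pair <- global_affine_align(parts_a, parts_b, id = "fixture")
  list(pair = pair, truth = truth, seq_a = parts_a, seq_b = parts_b)
}
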