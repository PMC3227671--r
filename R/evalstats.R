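# Scoring of detector output against simulation truth, permutation tests for
# proximity of calls to genomic features, inverted-repeat flank detection,
# divergence accounting and per-chromosome densities.

#' Score a call set against planted-inversion truth
#'
#' A truth is detected (TP) when at least one call in the same pair satisfies
#' the match rule; calls matching no truth are false positives.  The default
#' match rule requires the call's B-side interval to overlap the planted
#' interval extended by 50 bp on each side -- the difference-rich
#' neighbourhood the inversion creates -- since detected boundaries can
#' legitimately shift when segment ends are ambiguous (e.g. rotations of the
#' junction).  Use \code{\link{length_bounded_match_rule}} for a stricter
#' accounting of boundary accuracy.
#'
#' @param calls calls data frame with a \code{pair} column naming the source
#'   pair of each call.
#' @param truths data frame with columns pair, start, end (0-based half-open,
#'   B coordinates) and length.
#' @param match_rule function(call_start, call_end, call_length, truth_start,
#'   truth_end, truth_length) -> logical.
#' @param inversion_length reported size class (default: unique truth
#'   length).
#' @return object of class \code{eval_report}: inversion_length, n_pairs,
#'   true_positives, false_negatives, false_positives, sensitivity, ppv
#'   (with attribute \code{ppv_defined}).
#' @export
score_simulation <- function(calls, truths, match_rule = default_match_rule,
                             inversion_length = NULL) {
  stopifnot(all(c("pair", "start", "end", "length") %in% names(truths)))
  n_calls <- if (is.null(calls)) 0L else nrow(calls)
  call_matched <- rep(FALSE, n_calls)
  truth_hit <- rep(FALSE, nrow(truths))
  if (n_calls > 0L) {
    stopifnot("pair" %in% names(calls))
    for (ti in seq_len(nrow(truths))) {
      sel <- which(calls$pair == truths$pair[ti])
      for (ci in sel) {
        if (match_rule(calls$start_b[ci], calls$end_b[ci],
                       calls$length_bp[ci], truths$start[ti],
                       truths$end[ti], truths$length[ti])) {
          truth_hit[ti] <- TRUE
          call_matched[ci] <- TRUE
        }
      }
    }
  }
  tp <- sum(truth_hit); fn <- nrow(truths) - tp
  fp <- sum(!call_matched)
  ppv_defined <- (tp + fp) > 0L
  if (is.null(inversion_length))
    inversion_length <- if (nrow(truths) > 0L)
      as.integer(truths$length[1]) else NA_integer_
  structure(list(inversion_length = inversion_length,
                 n_pairs = length(unique(truths$pair)),
                 true_positives = tp, false_negatives = fn,
                 false_positives = fp,
                 sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NaN,
                 ppv = if (ppv_defined) tp / (tp + fp) else 1.0),
            class = "eval_report", ppv_defined = ppv_defined)
}

#' Default simulation match rule: B-side overlap with a 50 bp margin
#'
#' @param call_start,call_end,call_length call geometry (B side).
#' @param truth_start,truth_end,truth_length planted geometry.
#' @param margin neighbourhood allowance in bp (default 50, the candidate
#'   region extension).
#' @return logical.
#' @export
default_match_rule <- function(call_start, call_end, call_length,
                               truth_start, truth_end, truth_length,
                               margin = 50L) {
  call_start < truth_end + margin && truth_start - margin < call_end
}

#' Strict simulation match rule: overlap plus length agreement
#'
#' Overlap of at least 1 bp on the B side and call length within +/-50% of
#' the planted length.
#'
#' @inheritParams default_match_rule
#' @return logical.
#' @export
length_bounded_match_rule <- function(call_start, call_end, call_length,
                                      truth_start, truth_end, truth_length) {
  overlap <- call_start < truth_end && truth_start < call_end
  overlap && call_length >= 0.5 * truth_length &&
    call_length <= 1.5 * truth_length
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> inversion %s bp over %d pairs: ",
                     "TP %d FN %d FP %d | sensitivity %.3f PPV %.4f\n"),
              x$inversion_length, x$n_pairs, x$true_positives,
              x$false_negatives, x$false_positives, x$sensitivity, x$ppv))
  invisible(x)
}

empirical_p <- function(null_counts, observed) {
  (1 + sum(null_counts >= observed)) / (length(null_counts) + 1)
}

place_random_segments <- function(sizes, genome_sizes) {
  chroms <- names(genome_sizes)
  probs <- as.numeric(genome_sizes) / sum(as.numeric(genome_sizes))
  ch <- sample(chroms, length(sizes), replace = TRUE, prob = probs)
  # reject placements crossing the chromosome end by resampling the start
  start <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    lim <- genome_sizes[[ch[i]]] - sizes[i]
    while (lim < 0) {  # segment longer than the chromosome: redraw chrom
      ch[i] <- sample(chroms, 1L, prob = probs)
      lim <- genome_sizes[[ch[i]]] - sizes[i]
    }
    start[i] <- floor(runif(1, 0, lim + 1))
  }
  data.frame(chrom = ch, start = start, end = start + sizes,
             stringsAsFactors = FALSE)
}

segment_feature_distances <- function(segs, features) {
  # nearest-edge distance; 0 when a feature boundary lies inside the segment
  d <- rep(Inf, nrow(segs))
  by_chrom <- split(seq_len(nrow(features)), features$chrom)
  for (i in seq_len(nrow(segs))) {
    idx <- by_chrom[[segs$chrom[i]]]
    if (is.null(idx)) next
    edges <- c(features$start[idx], features$end[idx])
    if (any(edges >= segs$start[i] & edges <= segs$end[i])) { d[i] <- 0; next }
    # fully containing feature also means distance 0
    if (any(features$start[idx] <= segs$start[i] &
            features$end[idx] >= segs$end[i])) { d[i] <- 0; next }
    d[i] <- min(abs(edges - segs$start[i]), abs(edges - segs$end[i]))
  }
  d
}

#' Random-placement test for proximity of calls to features
#'
#' Distances from each call to the nearest feature edge are binned every
#' \code{bin_bp}; the null distribution comes from \code{n_trials} uniform
#' placements of segments with the same size spectrum.  The empirical
#' per-bin p-value is the fraction of trials reaching the observed count
#' (with the standard +1 correction, so p is never below
#' \code{1/(n_trials+1)}).
#'
#' @param calls data frame with chrom_a/start_a/end_a columns (A-side
#'   genome coordinates), or chrom/start/end.
#' @param features BED-style data frame (chrom, start, end).
#' @param genome_sizes named vector of chromosome sizes.
#' @param n_trials number of random placements (default 1000).
#' @param bin_bp distance bin width (default 100).
#' @param n_bins number of bins reported.
#' @return list with \code{observed} counts per bin, \code{p} per bin,
#'   \code{null_mean}, and the bin breaks.
#' @export
feature_proximity_test <- function(calls, features, genome_sizes,
                                   n_trials = 1000L, bin_bp = 100L,
                                   n_bins = 20L) {
  if (nrow(features) == 0L) stop("features are empty")
  segs <- normalize_segs(calls)
  bin_of <- function(d) pmin(floor(d / bin_bp), n_bins - 1L)
  tab <- function(d) tabulate(bin_of(d) + 1L, nbins = n_bins)
  observed <- tab(segment_feature_distances(segs, features))
  null_counts <- matrix(0L, n_trials, n_bins)
  for (t in seq_len(n_trials)) {
    rnd <- place_random_segments(segs$end - segs$start, genome_sizes)
    null_counts[t, ] <- tab(segment_feature_distances(rnd, features))
  }
  p <- vapply(seq_len(n_bins), function(b)
    empirical_p(null_counts[, b], observed[b]), 0)
  list(observed = observed, p = p, null_mean = colMeans(null_counts),
       breaks = seq(0L, by = bin_bp, length.out = n_bins + 1L))
}

normalize_segs <- function(calls) {
  if (all(c("chrom", "start", "end") %in% names(calls)))
    calls[, c("chrom", "start", "end")]
  else
    data.frame(chrom = calls$chrom_a, start = calls$start_a,
               end = calls$end_a, stringsAsFactors = FALSE)
}

has_inverted_repeat <- function(left, right, min_repeat) {
  nl <- nchar(left)
  if (nl < min_repeat || nchar(right) < min_repeat) return(FALSE)
  rc_right <- reverse_complement(right)
  for (s in 1:(nl - min_repeat + 1L)) {
    if (grepl(substr(left, s, s + min_repeat - 1L), rc_right,
              fixed = TRUE)) return(TRUE)
  }
  FALSE
}

#' Inverted repeats flanking the called inversions
#'
#' A call is flagged when an exact reverse-complement match of at least
#' \code{min_repeat} bp exists between its 5' and 3' flanks (a window of
#' \code{window} bp immediately outside each end), the signature of
#' cruciform-mediated inversion.  Significance comes from the same
#' random-placement null as \code{\link{feature_proximity_test}}.
#'
#' @param calls data frame with chrom/start/end (or chrom_a/start_a/end_a).
#' @param sequences named list of chromosome sequences (plain strings).
#' @param min_repeat minimum exact repeat length (default 10).
#' @param window flank window in bp (default 30).
#' @param n_trials random placements for the null (default 1000).
#' @return list with \code{n_flagged}, \code{flags}, \code{p_value}, and
#'   \code{null_counts}.
#' @export
inverted_repeat_flank_test <- function(calls, sequences, min_repeat = 10L,
                                       window = 30L, n_trials = 1000L) {
  segs <- normalize_segs(calls)
  sizes <- vapply(sequences, nchar, 0L)
  flag_segs <- function(s) {
    vapply(seq_len(nrow(s)), function(i) {
      seq <- sequences[[s$chrom[i]]]
      if (is.null(seq)) stop("missing sequence for ", s$chrom[i])
      left <- substr(seq, max(1L, s$start[i] - window + 1L), s$start[i])
      right <- substr(seq, s$end[i] + 1L,
                      min(nchar(seq), s$end[i] + window))
      has_inverted_repeat(left, right, min_repeat)
    }, TRUE)
  }
  flags <- flag_segs(segs)
  null_counts <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    rnd <- place_random_segments(segs$end - segs$start, as.list(sizes))
    null_counts[t] <- sum(flag_segs(rnd))
  }
  list(n_flagged = sum(flags), flags = flags,
       p_value = empirical_p(null_counts, sum(flags)),
       null_counts = null_counts)
}

#' Nucleotide divergence of a set of pairwise alignments
#'
#' Mismatched columns divided by aligned (non-gap in both rows) columns,
#' optionally excluding columns that fall inside call intervals (A-side
#' genome coordinates), which quantifies how much of the divergence is
#' contributed by inversions.
#'
#' @param pairs list of \code{\link{gapped_pair}} (or one pair).
#' @param exclude optional calls data frame; columns inside
#'   [start_a, end_a) on chrom_a are excluded.
#' @return divergence in [0, 1].
#' @export
divergence <- function(pairs, exclude = NULL) {
  if (inherits(pairs, "gapped_pair")) pairs <- list(pairs)
  mm_tot <- 0; cols_tot <- 0
  for (p in pairs) {
    ca <- charvec(p$text_a); cb <- charvec(p$text_b)
    aligned <- ca != "-" & cb != "-"
    keep <- aligned
    if (!is.null(exclude) && nrow(exclude) > 0L) {
      maps <- column_maps(p)
      pos <- p$loc_a$start + maps$a
      excl <- rep(FALSE, length(ca))
      sel <- exclude$chrom_a == p$loc_a$chrom
      for (i in which(sel))
        excl <- excl | (!is.na(pos) & pos >= exclude$start_a[i] &
                          pos < exclude$end_a[i])
      keep <- keep & !excl
    }
    mm_tot <- mm_tot + sum(keep & (ca != cb | ca == "N" | cb == "N"))
    cols_tot <- cols_tot + sum(keep)
  }
  if (cols_tot == 0) stop("zero aligned columns")
  mm_tot / cols_tot
}

#' Per-chromosome call densities with bootstrap intervals
#'
#' Calls per Mb for each chromosome, a bootstrap (resampling calls) standard
#' error, and an empirical p-value per chromosome against uniform random
#' placement proportional to chromosome size.
#'
#' @param calls data frame with chrom/start/end (or chrom_a/start_a/end_a).
#' @param chrom_sizes named vector of chromosome sizes in bp.
#' @param n_boot bootstrap resamples (default 1000).
#' @param n_trials random-placement trials for p-values (default 1000).
#' @return data frame: chrom, n, density (calls/Mb), boot_se, p_enriched,
#'   p_depleted.
#' @export
density_by_chrom <- function(calls, chrom_sizes, n_boot = 1000L,
                             n_trials = 1000L) {
  segs <- normalize_segs(calls)
  if (nrow(segs) > 0L && !all(segs$chrom %in% names(chrom_sizes)))
    stop("call on unknown chromosome")
  chroms <- names(chrom_sizes)
  mb <- as.numeric(chrom_sizes) / 1e6
  count_by <- function(ch) tabulate(match(ch, chroms), length(chroms))
  n_obs <- count_by(segs$chrom)
  dens <- n_obs / mb
  boot <- matrix(0, n_boot, length(chroms))
  if (nrow(segs) > 0L) {
    for (b in seq_len(n_boot))
      boot[b, ] <- count_by(sample(segs$chrom, nrow(segs),
                                   replace = TRUE)) / mb
  }
  null <- matrix(0L, n_trials, length(chroms))
  probs <- as.numeric(chrom_sizes) / sum(as.numeric(chrom_sizes))
  for (t in seq_len(n_trials))
    null[t, ] <- count_by(sample(chroms, nrow(segs), replace = TRUE,
                                 prob = probs))
  data.frame(chrom = chroms, n = n_obs, density = dens,
             boot_se = apply(boot, 2, stats::sd),
             p_enriched = vapply(seq_along(chroms), function(i)
               empirical_p(null[, i], n_obs[i]), 0),
             p_depleted = vapply(seq_along(chroms), function(i)
               (1 + sum(null[, i] <= n_obs[i])) / (n_trials + 1), 0),
             stringsAsFactors = FALSE)
}
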