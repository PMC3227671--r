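# Inverted-homology search inside candidate regions and classification of
# ultramicro inversion calls under criteria (i) (trio) and (ii) (duo,
# partially palindromic), plus the AT mono-/dinucleotide repeat exclusion
# filters.

#' Detector configuration
#'
#' Thresholds of the admission criteria and the blastn-like scoring of the
#' seeded inverted search (word size 5; match +1, mismatch -3, gap open 5,
#' gap extend 2).
#'
#' @param word_size exact-match seed length (>= 4).
#' @param min_inverted_similarity criterion (i): inverted similarity must
#'   exceed this (default 0.95).
#' @param similarity_ratio criterion (i): inverted similarity must exceed
#'   this multiple of the forward similarity (default 1.25).
#' @param min_overlap_fraction criterion (i): minimum fraction of the inverted
#'   region aligned against bases (not gaps) in the forward alignment when
#'   not completely included (default 0.80).
#' @param duo_identity_fraction criterion (ii): the identically aligned
#'   sandwiched run must exceed this fraction of the segment (default 0.50).
#' @param min_inversion_length,max_inversion_length call length bounds
#'   (defaults 5 and 125).
#' @param match,mismatch,gap_open,gap_extend seeded-search scoring.
#' @param xdrop ungapped extension X-drop.
#' @param max_hits HSPs carried into gapped extension.
#' @param ext_cap cap on gapped extension length per side.
#' @param max_n_fraction regions with a higher fraction of N are skipped.
#' @param evalue_max hits with a Karlin-Altschul expectation value
#'   \eqn{E = K m n e^{-\lambda S}} above this are not reported, mirroring
#'   blastn's default expectation threshold of 10; this is what limits the
#'   detection of the very shortest (5-6 bp) inversions, whose hits score
#'   near the reporting limit.  Set to \code{Inf} to disable.
#' @param ka_lambda,ka_k Karlin-Altschul parameters for the +1/-3 scoring.
#' @return object of class \code{detector_config}.
#' @export
detector_config <- function(word_size = 5L, min_inverted_similarity = 0.95,
                            similarity_ratio = 1.25,
                            min_overlap_fraction = 0.80,
                            duo_identity_fraction = 0.50,
                            min_inversion_length = 5L,
                            max_inversion_length = 125L,
                            match = 1L, mismatch = -3L, gap_open = 5L,
                            gap_extend = 2L, xdrop = 20L, max_hits = 16L,
                            ext_cap = 200L, max_n_fraction = 0.5,
                            evalue_max = 10, ka_lambda = 1.374,
                            ka_k = 0.711) {
  stopifnot(word_size >= 4L, min_inverted_similarity > 0,
            min_inverted_similarity <= 1, similarity_ratio > 0,
            min_overlap_fraction > 0, min_overlap_fraction <= 1,
            duo_identity_fraction > 0, duo_identity_fraction <= 1,
            min_inversion_length >= 1L,
            max_inversion_length >= min_inversion_length,
            match > 0L, mismatch < 0L, gap_open >= 0L, gap_extend >= 0L)
  structure(list(word_size = as.integer(word_size),
                 min_inverted_similarity = min_inverted_similarity,
                 similarity_ratio = similarity_ratio,
                 min_overlap_fraction = min_overlap_fraction,
                 duo_identity_fraction = duo_identity_fraction,
                 min_inversion_length = as.integer(min_inversion_length),
                 max_inversion_length = as.integer(max_inversion_length),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 xdrop = as.integer(xdrop), max_hits = as.integer(max_hits),
                 ext_cap = as.integer(ext_cap),
                 max_n_fraction = max_n_fraction,
                 evalue_max = evalue_max, ka_lambda = ka_lambda,
                 ka_k = ka_k),
            class = "detector_config")
}

#' Reverse complement
#'
#' @param s nucleotide string(s) over A,C,G,T,N (case-insensitive).
#' @return reverse-complemented string(s).
#' @export
reverse_complement <- function(s) {
  s <- toupper(s)
  if (any(grepl("[^ACGTN]", s)))
    stop("invalid character; alphabet is A,C,G,T,N")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Column-identity similarity of two aligned strings
#'
#' Identical columns divided by total columns; gap columns and columns
#' containing 'N' count as non-identical.
#'
#' @param aligned_a,aligned_b equal-length gapped strings.
#' @return similarity in [0,1].
#' @export
similarity <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned strings must have equal length")
  if (nchar(aligned_a) == 0L) return(NaN)
  ca <- charvec(toupper(aligned_a)); cb <- charvec(toupper(aligned_b))
  mean(ca == cb & ca != "-" & ca != "N")
}

#' Seeded inverted-homology search
#'
#' blastn-like local search: exact \code{word_size}-mer seeds, ungapped
#' X-drop extension, gapped extension of the top HSPs.  The query is the
#' reverse complement of one species' ungapped candidate segment and the
#' target the other species' segment.
#'
#' @param query,target ungapped nucleotide strings.
#' @param cfg a \code{\link{detector_config}}.
#' @return data frame of hits sorted by score (ties by t_start, q_start):
#'   q_start, q_end, t_start, t_end (0-based half-open ungapped coordinates),
#'   score, similarity, aligned_q, aligned_t.
#' @export
seed_extend_search <- function(query, target, cfg = detector_config()) {
  res <- .seed_extend_cpp(toupper(query), toupper(target), cfg$word_size,
                          cfg$match, cfg$mismatch, cfg$gap_open,
                          cfg$gap_extend, cfg$max_hits, cfg$ext_cap,
                          cfg$xdrop)
  hits <- as.data.frame(res, stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    hits$similarity <- numeric(0)
    hits$evalue <- numeric(0)
    return(hits)
  }
  hits$similarity <- mapply(similarity, hits$aligned_q, hits$aligned_t,
                            USE.NAMES = FALSE)
  hits$evalue <- ka_evalue(hits$score, nchar(query), nchar(target), cfg)
  hits
}

# Karlin-Altschul expectation value E = K m n exp(-lambda S), the criterion
# blastn uses to decide which hits are reported.
ka_evalue <- function(score, m, n, cfg) {
  cfg$ka_k * m * n * exp(-cfg$ka_lambda * score)
}

# Extract the ungapped segments of a region plus coordinate scaffolding.
region_context <- function(pair, region, maps = NULL) {
  if (is.null(maps)) maps <- column_maps(pair)
  cols <- (region$col_start + 1L):region$col_end  # 1-based indices
  ca <- charvec(pair$text_a)[cols]; cb <- charvec(pair$text_b)[cols]
  a_keep <- ca != "-"; b_keep <- cb != "-"
  seg_a <- paste(ca[a_keep], collapse = "")
  seg_b <- paste(cb[b_keep], collapse = "")
  # alignment column (0-based) of each segment position
  col_of_a <- (cols - 1L)[a_keep]
  col_of_b <- (cols - 1L)[b_keep]
  # genome offsets of first segment base
  a0 <- if (any(a_keep)) maps$a[cols[a_keep][1]] else NA_integer_
  b0 <- if (any(b_keep)) maps$b[cols[b_keep][1]] else NA_integer_
  list(seg_a = seg_a, seg_b = seg_b, col_of_a = col_of_a, col_of_b = col_of_b,
       a0 = a0, b0 = b0, gap_b = (cb == "-"), gap_a = (ca == "-"),
       cols0 = cols - 1L, ca = ca, cb = cb)
}

# Map hit coordinates: target was seg_a, query was revcomp(seg_b).
hit_b_range <- function(hit, len_b) {
  c(len_b - hit$q_end, len_b - hit$q_start)
}

br_range <- function(hit, ctx) hit_b_range(hit, nchar(ctx$seg_b))

similarity_over_cols <- function(pair, col_lo, col_hi) {
  # columns 0-based half-open
  similarity(substr(pair$text_a, col_lo + 1L, col_hi),
             substr(pair$text_b, col_lo + 1L, col_hi))
}

make_call <- function(pair, ctx, hit, criterion, sim_fwd) {
  len_b <- nchar(ctx$seg_b)
  br <- hit_b_range(hit, len_b)
  a_lo <- ctx$a0 + hit$t_start; a_hi <- ctx$a0 + hit$t_end
  b_lo <- ctx$b0 + br[1]; b_hi <- ctx$b0 + br[2]
  seg_a <- substr(ctx$seg_a, hit$t_start + 1L, hit$t_end)
  seg_b <- substr(ctx$seg_b, br[1] + 1L, br[2])
  data.frame(id = pair$id, chrom_a = pair$loc_a$chrom,
             start_a = pair$loc_a$start + a_lo,
             end_a = pair$loc_a$start + a_hi,
             chrom_b = pair$loc_b$chrom,
             start_b = pair$loc_b$start + b_lo,
             end_b = pair$loc_b$start + b_hi,
             length_bp = hit$t_end - hit$t_start,
             criterion = criterion,
             similarity_inverted = hit$similarity,
             similarity_forward = sim_fwd,
             at_exclusive = FALSE, lineage = NA_character_,
             seg_a = seg_a, seg_b = seg_b, stringsAsFactors = FALSE)
}

#' Classify a trio candidate region (criterion i)
#'
#' Searches the region for an inverted local alignment and admits a call when
#' the best hit (a) lies on forward-aligned bases, completely or with more
#' than \code{min_overlap_fraction} of the inverted region (the rest being
#' aligned as gaps); (b) has inverted similarity above
#' \code{min_inverted_similarity}; (c) exceeds \code{similarity_ratio} times
#' the similarity of the corresponding forward sub-alignment; and (d) whose
#' forward sub-alignment spans a seeding trio.
#'
#' @param region one row of \code{\link{find_candidate_regions}} output (as a
#'   list), with kind "trio".
#' @param pair the \code{\link{gapped_pair}}.
#' @param cfg a \code{\link{detector_config}}.
#' @param maps optional precomputed \code{column_maps(pair)}.
#' @return a one-row calls data frame, or \code{NULL}.
#' @export
classify_trio_candidate <- function(region, pair, cfg = detector_config(),
                                    maps = NULL) {
  ctx <- region_context(pair, region, maps)
  if (!segments_searchable(ctx, cfg)) return(NULL)
  hits <- seed_extend_search(reverse_complement(ctx$seg_b), ctx$seg_a, cfg)
  if (nrow(hits) == 0L) return(NULL)
  trio_spans <- lapply(Filter(function(s) s$type == "trio", region$seeds),
                       `[[`, "span")
  for (h in seq_len(nrow(hits))) {
    hit <- hits[h, ]
    if (hit$evalue > cfg$evalue_max) next
    len_bp <- hit$t_end - hit$t_start
    if (len_bp < cfg$min_inversion_length ||
        len_bp > cfg$max_inversion_length) next
    if (hit$similarity <= cfg$min_inverted_similarity) next
    # forward sub-alignment spanning the hit's A positions
    cols_a <- ctx$col_of_a[(hit$t_start + 1L):hit$t_end]
    f_lo <- cols_a[1]; f_hi <- cols_a[length(cols_a)] + 1L
    sim_fwd <- similarity_over_cols(pair, f_lo, f_hi)
    if (!(hit$similarity > cfg$similarity_ratio * sim_fwd)) next
    # overlap rule: the inverted region (the hit's B-side bases) must lie
    # within its *corresponding* forward alignment region (the columns of
    # the hit's A-side span) -- completely, or over min_overlap_fraction
    # with the remainder aligned as gaps in the forward alignment.  This
    # rejects off-diagonal hits that pair distant segments of the region
    # while tolerating partial gap-staggering of the true segment.
    cols_b <- ctx$col_of_b[(br_range(hit, ctx)[1] + 1L):br_range(hit, ctx)[2]]
    inside <- cols_b >= f_lo & cols_b < f_hi
    rest_gapped <- all(ctx$gap_a[cols_b[!inside] - region$col_start + 1L])
    b_frac <- mean(inside)
    if (!(b_frac == 1 ||
          (b_frac > cfg$min_overlap_fraction && rest_gapped))) next
    # the forward sub-alignment must include a seeding trio
    included <- any(vapply(trio_spans, function(s)
      s[1] >= f_lo && s[2] <= f_hi, TRUE))
    if (!included) next
    return(make_call(pair, ctx, hit, "i", sim_fwd))
  }
  NULL
}

segments_searchable <- function(ctx, cfg) {
  na <- nchar(ctx$seg_a); nb <- nchar(ctx$seg_b)
  if (na < cfg$word_size || nb < cfg$word_size) return(FALSE)
  n_frac <- max(mean(charvec(ctx$seg_a) == "N"),
                mean(charvec(ctx$seg_b) == "N"))
  n_frac <= cfg$max_n_fraction
}

#' Classify a duo candidate region (criterion ii)
#'
#' Partially palindromic inversions: the forward alignment shows two gap
#' blocks on different rows sandwiching an identically aligned run.  A call
#' requires an inverted hit with similarity exactly 1 that covers the whole
#' forwardly aligned duo span in both species, with the sandwiched identical
#' run longer than \code{duo_identity_fraction} of the segment.
#'
#' @inheritParams classify_trio_candidate
#' @return a one-row calls data frame, or \code{NULL}.
#' @export
classify_duo_candidate <- function(region, pair, cfg = detector_config(),
                                   maps = NULL) {
  ctx <- region_context(pair, region, maps)
  if (!segments_searchable(ctx, cfg)) return(NULL)
  hits <- seed_extend_search(reverse_complement(ctx$seg_b), ctx$seg_a, cfg)
  if (nrow(hits) == 0L) return(NULL)
  len_b <- nchar(ctx$seg_b)
  best <- NULL
  for (seed in Filter(function(s) s$type == "duo", region$seeds)) {
    span_lo <- seed$g1[1]; span_hi <- seed$g2[2]  # duo span, 0-based cols
    sandwich <- seed$g2[1] - seed$g1[2]           # identical columns between
    if (sandwich < 1L) next
    # the corresponding forward region consists of the duo of gap blocks
    # with the sandwiched run between: the inverted hit must span all of it
    rel <- (span_lo:(span_hi - 1L)) - region$col_start + 1L
    a_pos <- ctx$cols0[rel][!ctx$gap_a[rel]]
    b_pos <- ctx$cols0[rel][!ctx$gap_b[rel]]
    a_rng <- range(match(a_pos, ctx$col_of_a))
    b_rng <- range(match(b_pos, ctx$col_of_b))
    for (h in seq_len(nrow(hits))) {
      hit <- hits[h, ]
      if (hit$evalue > cfg$evalue_max) next
      if (hit$similarity < 1) next
      len_bp <- hit$t_end - hit$t_start
      if (len_bp < cfg$min_inversion_length ||
          len_bp > cfg$max_inversion_length) next
      # coverage: the inverted region must cover 100% of the forwardly
      # aligned (sandwiched) run in both species
      br <- hit_b_range(hit, len_b)
      if (!(hit$t_start <= a_rng[1] - 1L && hit$t_end >= a_rng[2])) next
      if (!(br[1] <= b_rng[1] - 1L && br[2] >= b_rng[2])) next
      if (!(sandwich > cfg$duo_identity_fraction * len_bp)) next
      sim_fwd <- similarity_over_cols(pair, span_lo, span_hi)
      cand <- make_call(pair, ctx, hit, "ii", sim_fwd)
      if (is.null(best) || cand$length_bp > best$length_bp) best <- cand
      break  # hits are score-sorted; first qualifying hit per seed
    }
  }
  best
}

#' AT mono-/dinucleotide repeat exclusion filter
#'
#' TRUE (discard) when the called segment pair is explainable without an
#' inversion: both segments are runs of A followed by runs of T (or T
#' followed by A) -- stretch/shrink of mononucleotide repeats -- or both are
#' strictly alternating AT dinucleotide repeats offset by one phase.
#'
#' @param seg_a,seg_b the two species' inverted segments.
#' @return logical; TRUE means the call should be discarded.
#' @export
at_repeat_filter <- function(seg_a, seg_b) {
  seg_a <- toupper(seg_a); seg_b <- toupper(seg_b)
  at_only <- grepl("^[AT]+$", seg_a) && grepl("^[AT]+$", seg_b)
  if (!at_only) return(FALSE)
  mono <- function(s) grepl("^A*T*$", s) || grepl("^T*A*$", s)
  if (mono(seg_a) && mono(seg_b)) return(TRUE)
  di <- function(s) !grepl("AA|TT", s)
  di(seg_a) && di(seg_b)
}

#' Is a call AT-exclusive?
#'
#' TRUE when both species' inverted segments consist of adenine and thymine
#' only.
#'
#' @param seg_a,seg_b the two species' inverted segments.
#' @return logical.
#' @export
classify_at_exclusive <- function(seg_a, seg_b) {
  grepl("^[AT]+$", toupper(seg_a)) && grepl("^[AT]+$", toupper(seg_b))
}

#' Scan a gapped pair for ultramicro inversions
#'
#' End-to-end detection on one local alignment: difference events, trio/duo
#' candidate regions, seeded inverted search, criteria (i)/(ii), AT repeat
#' filters, deduplication (overlapping trio/duo calls keep the higher
#' inverted similarity), and coordinate sorting.
#'
#' @param pair a \code{\link{gapped_pair}}.
#' @param rates a \code{\link{rate_params}}.
#' @param cfg a \code{\link{detector_config}}.
#' @param alpha,extension candidate-region parameters (defaults 0.05, 50).
#' @return calls data frame (0 rows when nothing is found); columns as in
#'   \code{\link{write_inversion_tsv}} plus seg_a/seg_b.
#' @export
scan_pair <- function(pair, rates, cfg = detector_config(), alpha = 0.05,
                      extension = 50L) {
  regions <- find_candidate_regions(pair, rates, alpha, extension)
  if (nrow(regions) == 0L) return(empty_calls())
  maps <- column_maps(pair)
  calls <- list()
  for (i in seq_len(nrow(regions))) {
    region <- as.list(regions[i, c("col_start", "col_end", "kind", "span_n",
                                   "probability")])
    region$seeds <- regions$seeds[[i]]
    call <- if (region$kind == "trio")
      classify_trio_candidate(region, pair, cfg, maps)
    else
      classify_duo_candidate(region, pair, cfg, maps)
    if (!is.null(call)) calls[[length(calls) + 1L]] <- call
  }
  if (length(calls) == 0L) return(empty_calls())
  calls <- do.call(rbind, calls)
  keep <- !mapply(at_repeat_filter, calls$seg_a, calls$seg_b)
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0L) return(empty_calls())
  calls$at_exclusive <- mapply(classify_at_exclusive, calls$seg_a,
                               calls$seg_b, USE.NAMES = FALSE)
  # dedupe overlapping calls across routes: higher similarity wins,
  # criterion i breaks ties
  ord <- order(-calls$similarity_inverted, calls$criterion, calls$start_a)
  calls <- calls[ord, , drop = FALSE]
  kept <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!kept[i]) next
    if (i < nrow(calls)) for (j in (i + 1L):nrow(calls)) {
      if (!kept[j]) next
      ov_a <- calls$start_a[i] < calls$end_a[j] &&
        calls$start_a[j] < calls$end_a[i]
      ov_b <- calls$start_b[i] < calls$end_b[j] &&
        calls$start_b[j] < calls$end_b[i]
      if (ov_a || ov_b) kept[j] <- FALSE
    }
  }
  calls <- calls[kept, , drop = FALSE]
  calls <- calls[order(calls$chrom_a, calls$start_a), , drop = FALSE]
  if (nrow(calls) > 0L)
    calls$id <- paste0(pair$id, ".", seq_len(nrow(calls)))
  rownames(calls) <- NULL
  calls
}
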