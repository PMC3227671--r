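# Lineage assignment of inversions by phylogenetic profiling against
# outgroup sequences (gorilla and/or orangutan), including the two
# incomplete-lineage-sorting patterns.

LINEAGE_LEVELS <- c("human", "chimpanzee", "human_gorilla",
                    "chimpanzee_gorilla", "unresolved", "no_outgroup")

#' Count differences between two rows of a multiple alignment
#'
#' Mismatch columns plus maximal gap blocks (a run of '-' in exactly one of
#' the two rows) within a column window.  Columns gapped in both rows are
#' ignored; 'N' never matches.
#'
#' @param msa a \code{\link{multiple_alignment}}.
#' @param row_i,row_j row indices or names.
#' @param col_start,col_end 0-based half-open column window (defaults: whole
#'   alignment).
#' @return integer difference count.
#' @export
count_pairwise_diffs <- function(msa, row_i, row_j, col_start = 0L,
                                 col_end = msa$column_count) {
  if (is.character(row_i)) row_i <- match(row_i, msa$names)
  if (is.character(row_j)) row_j <- match(row_j, msa$names)
  if (col_start < 0L || col_end > msa$column_count || col_start > col_end)
    stop("column window out of range")
  if (col_end == col_start) return(0L)
  ci <- charvec(msa$rows[[row_i]])[(col_start + 1L):col_end]
  cj <- charvec(msa$rows[[row_j]])[(col_start + 1L):col_end]
  gi <- ci == "-"; gj <- cj == "-"
  mm <- sum(!gi & !gj & (ci != cj | ci == "N" | cj == "N"))
  blocks <- function(g, other_g) {
    x <- g & !other_g
    if (!any(x)) return(0L)
    r <- rle(x)
    sum(r$values)
  }
  mm + blocks(gi, gj) + blocks(gj, gi)
}

# Verdict of one outgroup: which of human/chimpanzee carries the inverted
# (outgroup-discordant) state.  "fewer than two" differences = concordant,
# "three or more" = discordant; a count of exactly 2 is inconclusive.
outgroup_verdict <- function(d_human, d_chimp) {
  if (d_human <= 1L && d_chimp >= 3L) return("chimpanzee")
  if (d_chimp <= 1L && d_human >= 3L) return("human")
  NA_character_
}

#' Assign the lineage of an inversion from a multiple alignment
#'
#' Within the inversion's columns, an outgroup votes "chimpanzee" when it
#' differs from the chimpanzee row by three or more mismatches/gap blocks
#' while matching the human row with fewer than two (and vice versa).
#' Gorilla is the deciding outgroup; orangutan corroborates or, when it
#' contradicts gorilla, exposes incomplete lineage sorting:
#' gorilla says "chimpanzee" but orangutan says "human" means human and
#' gorilla share the inverted state (gene tree ((Human, Gorilla),
#' Chimpanzee) -> \code{human_gorilla}); the mirror image gives
#' \code{chimpanzee_gorilla}.  Orangutan-only profiles cannot produce the
#' ILS categories.
#'
#' @param msa a \code{\link{multiple_alignment}} whose row names include
#'   "human", "chimpanzee" and at least one of "gorilla", "orangutan"
#'   (case-insensitive prefixes).
#' @param inversion_cols 0-based half-open column window of the inversion.
#' @return one of "human", "chimpanzee", "human_gorilla",
#'   "chimpanzee_gorilla", "unresolved", "no_outgroup".
#' @export
assign_lineage <- function(msa, inversion_cols) {
  nm <- tolower(msa$names)
  find_row <- function(sp) {
    i <- which(startsWith(nm, sp))
    if (length(i) == 0L) NA_integer_ else i[1]
  }
  h <- find_row("human"); c_ <- find_row("chimp")
  if (is.na(h) || is.na(c_)) stop("msa must contain human and chimpanzee rows")
  g <- find_row("gorilla"); o <- find_row("orang")
  if (is.na(g) && is.na(o)) return("no_outgroup")
  cs <- inversion_cols[1]; ce <- inversion_cols[2]
  verdict <- function(out_row) {
    outgroup_verdict(count_pairwise_diffs(msa, h, out_row, cs, ce),
                     count_pairwise_diffs(msa, c_, out_row, cs, ce))
  }
  vg <- if (!is.na(g)) verdict(g) else NA_character_
  vo <- if (!is.na(o)) verdict(o) else NA_character_
  if (!is.na(vg) && !is.na(vo)) {
    if (vg == vo) return(vg)
    if (vg == "chimpanzee" && vo == "human") return("human_gorilla")
    return("chimpanzee_gorilla")
  }
  if (!is.na(vg)) return(vg)
  if (!is.na(vo)) return(vo)
  "unresolved"
}

#' Annotate a call set with lineages from outgroup alignments
#'
#' For each call, outgroup alignments overlapping the call's human (A-side)
#' interval are gathered by single linkage, the human/chimpanzee/outgroup
#' segments around the inversion are extracted, star-aligned around the
#' human row, and \code{\link{assign_lineage}} is applied to the inversion's
#' columns.  Calls with no overlapping outgroup alignment get
#' \code{no_outgroup}.
#'
#' @param calls calls data frame from \code{\link{scan_pair}}.
#' @param pairs named list mapping each call's \code{id} prefix (the source
#'   pair id) to its \code{\link{gapped_pair}}, or a single
#'   \code{gapped_pair} when all calls share one source alignment.
#' @param outgroup_pairs named list of outgroup \code{gapped_pair} lists:
#'   e.g. \code{list(gorilla = list(...), orangutan = list(...))}, each pair
#'   aligning human (row a, genome coordinates in loc_a) to the outgroup
#'   (row b).
#' @param flank bases of human flank added on each side for alignment
#'   context.
#' @param scoring star-alignment scoring.
#' @return the calls data frame with the \code{lineage} column filled.
#' @export
profile_callset <- function(calls, pairs, outgroup_pairs, flank = 20L,
                            scoring = align_scoring()) {
  if (nrow(calls) == 0L) return(calls)
  single <- inherits(pairs, "gapped_pair")
  for (i in seq_len(nrow(calls))) {
    pair <- if (single) pairs else pairs[[sub("\\.[0-9]+$", "", calls$id[i])]]
    calls$lineage[i] <- profile_one_call(calls[i, ], pair, outgroup_pairs,
                                         flank, scoring)
  }
  calls
}

extract_b_segment <- function(gp, h_lo, h_hi) {
  # human positions [h_lo, h_hi) -> the other row's ungapped segment spanning
  # the same columns; NULL if the pair does not cover the window
  if (gp$loc_a$start > h_lo || gp$loc_a$end < h_hi) return(NULL)
  cols <- genome_to_column(gp, c(h_lo, h_hi - 1L), "a")
  txt <- substr(gp$text_b, cols[1] + 1L, cols[2] + 1L)
  gsub("-", "", txt, fixed = TRUE)
}

profile_one_call <- function(call, pair, outgroup_pairs, flank, scoring) {
  h_lo <- max(pair$loc_a$start, call$start_a - flank)
  h_hi <- min(pair$loc_a$end, call$end_a + flank)
  # human segment from the call pair's A row
  cols <- genome_to_column(pair, c(h_lo, h_hi - 1L), "a")
  human <- gsub("-", "",
                substr(pair$text_a, cols[1] + 1L, cols[2] + 1L), fixed = TRUE)
  chimp <- extract_b_segment(pair, h_lo, h_hi)
  seqs <- list(human = human, chimpanzee = chimp)
  for (sp in names(outgroup_pairs)) {
    gps <- outgroup_pairs[[sp]]
    if (inherits(gps, "gapped_pair")) gps <- list(gps)
    # single linkage: any outgroup alignment overlapping the human interval
    for (gp in gps) {
      if (gp$loc_a$chrom != call$chrom_a) next
      if (gp$loc_a$start >= h_hi || gp$loc_a$end <= h_lo) next
      seg <- extract_b_segment(gp, h_lo, h_hi)
      if (!is.null(seg) && nchar(seg) > 0L) { seqs[[sp]] <- seg; break }
    }
  }
  if (length(seqs) < 3L) return("no_outgroup")
  if (any(!nzchar(unlist(seqs)))) return("unresolved")
  msa <- star_multi_align(seqs, reference = "human", scoring = scoring)
  # inversion columns: positions of the inversion within the human segment
  ref_cols <- which(charvec(msa$rows[[1]]) != "-")  # 1-based columns
  lo <- call$start_a - h_lo   # 0-based offset of inversion in human segment
  hi <- call$end_a - h_lo
  cs <- ref_cols[lo + 1L] - 1L
  ce <- ref_cols[hi]
  assign_lineage(msa, c(cs, ce))
}
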