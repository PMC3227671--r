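# Difference-event enumeration and the trio/duo probability scan that yields
# difference-rich candidate regions.
#
# Null model: mismatches and gap blocks are i.i.d. per alignment site with
# density p_d (all difference events) and p_g (gap blocks only).  A trio of
# events packed into n columns is surprising when P_trio(n) < alpha; a duo of
# gap blocks on opposite rows is surprising when P_duo(n) < alpha.

#' Per-site difference densities
#'
#' @param p_d average number of mismatches plus gap blocks per alignment site.
#' @param p_g average number of gap blocks per alignment site.
#' @return object of class \code{rate_params}.
#' @export
rate_params <- function(p_d, p_g) {
  if (!(p_d > 0 && p_d < 1 && p_g > 0 && p_g <= p_d))
    stop("need 0 < p_g <= p_d < 1")
  structure(list(p_d = p_d, p_g = p_g), class = "rate_params")
}

#' Enumerate mismatches and gap blocks in a gapped pair
#'
#' A mismatch is a column with two different non-gap bases ('N' never
#' matches); a gap block is a maximal run of '-' in one row.
#'
#' @param pair a \code{\link{gapped_pair}}.
#' @return data frame with columns kind ("mismatch"/"gap_block"), col_start,
#'   col_end (0-based half-open alignment columns) and gap_row
#'   ("a"/"b"/"none"), sorted by col_start.
#' @export
find_difference_events <- function(pair) {
  ca <- charvec(pair$text_a); cb <- charvec(pair$text_b)
  ga <- ca == "-"; gb <- cb == "-"
  mm <- !ga & !gb & (ca != cb | ca == "N" | cb == "N")
  starts <- integer(0); ends <- integer(0); kinds <- character(0)
  rows <- character(0)
  if (any(mm)) {
    w <- which(mm) - 1L
    starts <- c(starts, w); ends <- c(ends, w + 1L)
    kinds <- c(kinds, rep("mismatch", length(w)))
    rows <- c(rows, rep("none", length(w)))
  }
  for (row in c("a", "b")) {
    g <- if (row == "a") ga else gb
    if (any(g)) {
      r <- rle(g)
      re <- cumsum(r$lengths); rs <- re - r$lengths
      keep <- r$values
      starts <- c(starts, rs[keep]); ends <- c(ends, re[keep])
      kinds <- c(kinds, rep("gap_block", sum(keep)))
      rows <- c(rows, rep(row, sum(keep)))
    }
  }
  ev <- data.frame(kind = kinds, col_start = as.integer(starts),
                   col_end = as.integer(ends), gap_row = rows,
                   stringsAsFactors = FALSE)
  ev[order(ev$col_start, ev$col_end), , drop = FALSE]
}

#' Probability of a trio of difference events within n sites
#'
#' Probability that, given a difference event at a site, at least two further
#' events fall within the following n-1 sites under the i.i.d. per-site null
#' with density \code{p_d}:
#' \deqn{P_{trio}(n) = 1 - (1-p_d)^{n-1} - (n-1) p_d (1-p_d)^{n-2}.}
#'
#' @param n span in alignment columns from the first to the last event of the
#'   trio, inclusive (n >= 3); vectorised.
#' @param p_d per-site difference density in (0,1).
#' @return probabilities in (0,1).
#' @export
p_trio <- function(n, p_d) {
  if (!(p_d > 0 && p_d < 1)) stop("p_d must be in (0,1)")
  if (any(n < 3)) stop("n must be >= 3")
  1 - (1 - p_d)^(n - 1) - (n - 1) * p_d * (1 - p_d)^(n - 2)
}

#' Probability of a duo of gap blocks within n sites
#'
#' \deqn{P_{duo}(n) = 1 - (1-p_g)^{n-1}.}
#'
#' @param n span in alignment columns (n >= 2); vectorised.
#' @param p_g per-site gap-block density in (0,1).
#' @return probabilities in (0,1).
#' @export
p_duo <- function(n, p_g) {
  if (!(p_g > 0 && p_g < 1)) stop("p_g must be in (0,1)")
  if (any(n < 2)) stop("n must be >= 2")
  1 - (1 - p_g)^(n - 1)
}

#' Estimate difference densities from alignments
#'
#' Recomputes \code{p_d} and \code{p_g} as (mismatches + gap blocks) / columns
#' and gap blocks / columns over a set of pairs.  Difference-free input is an
#' error, since the null model needs p in (0,1).
#'
#' @param pairs list of \code{\link{gapped_pair}} (or a single pair).
#' @return a \code{\link{rate_params}}.
#' @export
estimate_rates <- function(pairs) {
  if (inherits(pairs, "gapped_pair")) pairs <- list(pairs)
  if (length(pairs) == 0L) stop("need at least one pair")
  tot_cols <- 0; tot_ev <- 0; tot_gap <- 0
  for (p in pairs) {
    ev <- find_difference_events(p)
    tot_cols <- tot_cols + nchar(p$text_a)
    tot_ev <- tot_ev + nrow(ev)
    tot_gap <- tot_gap + sum(ev$kind == "gap_block")
  }
  if (tot_cols == 0L) stop("zero alignment columns")
  if (tot_ev == 0L)
    stop("no difference events found; p_d = 0 is outside the model")
  p_g <- max(tot_gap, 1L) / tot_cols  # clamp: p_g = 0 breaks the duo model
  rate_params(tot_ev / tot_cols, p_g)
}

# qualifying trio composition given kinds and gap rows of three consecutive
# events: 3 mismatches; 2 mismatches + 1 gap block; 1 mismatch + 2 gap blocks
# in different rows.
trio_qualifies <- function(kinds, rows) {
  ng <- sum(kinds == "gap_block")
  if (ng == 0L) return(TRUE)
  if (ng == 1L) return(TRUE)
  if (ng == 2L) {
    gr <- rows[kinds == "gap_block"]
    return(gr[1] != gr[2])
  }
  FALSE
}

#' Extract difference-rich candidate regions
#'
#' Scans the sorted event list: every window of three consecutive events with
#' a qualifying composition and \code{p_trio(n) < alpha} seeds a trio
#' candidate; every pair of consecutive gap blocks on different rows with
#' \code{p_duo(n) < alpha} (the sandwiched columns are identically aligned by
#' construction) seeds a duo candidate.  Overlapping candidates of the same
#' kind are merged (single linkage), extended by \code{extension} columns on
#' each side, clipped to the alignment, and re-merged.
#'
#' @param pair a \code{\link{gapped_pair}}.
#' @param rates a \code{\link{rate_params}}.
#' @param alpha significance threshold (default 0.05).
#' @param extension columns added to each side (default 50).
#' @param events optional precomputed \code{\link{find_difference_events}}.
#' @return data frame with columns col_start, col_end, kind, span_n,
#'   probability, and a list-column \code{seeds} holding, per region, the
#'   seed windows (trio event spans, or duo gap-block geometry).
#' @export
find_candidate_regions <- function(pair, rates, alpha = 0.05, extension = 50L,
                                   events = NULL) {
  stopifnot(inherits(rates, "rate_params"))
  L <- nchar(pair$text_a)
  ev <- if (is.null(events)) find_difference_events(pair) else events
  n_ev <- nrow(ev)
  cand <- list()
  if (n_ev >= 3L) {
    for (i in seq_len(n_ev - 2L)) {
      k <- ev$kind[i:(i + 2L)]; r <- ev$gap_row[i:(i + 2L)]
      if (!trio_qualifies(k, r)) next
      n <- ev$col_end[i + 2L] - ev$col_start[i]
      pr <- p_trio(n, rates$p_d)
      if (pr < alpha)
        cand[[length(cand) + 1L]] <- list(
          start = ev$col_start[i], end = ev$col_end[i + 2L], kind = "trio",
          span_n = n, probability = pr,
          seed = list(type = "trio", span = c(ev$col_start[i],
                                              ev$col_end[i + 2L])))
    }
  }
  if (n_ev >= 2L) {
    for (i in seq_len(n_ev - 1L)) {
      if (ev$kind[i] != "gap_block" || ev$kind[i + 1L] != "gap_block") next
      if (ev$gap_row[i] == ev$gap_row[i + 1L]) next
      n <- ev$col_end[i + 1L] - ev$col_start[i]
      pr <- p_duo(n, rates$p_g)
      if (pr < alpha)
        cand[[length(cand) + 1L]] <- list(
          start = ev$col_start[i], end = ev$col_end[i + 1L], kind = "duo",
          span_n = n, probability = pr,
          seed = list(type = "duo",
                      g1 = c(ev$col_start[i], ev$col_end[i]),
                      g2 = c(ev$col_start[i + 1L], ev$col_end[i + 1L]),
                      gap_rows = ev$gap_row[i:(i + 1L)]))
    }
  }
  if (length(cand) == 0L)
    return(data.frame(col_start = integer(0), col_end = integer(0),
                      kind = character(0), span_n = integer(0),
                      probability = numeric(0),
                      seeds = I(list()), stringsAsFactors = FALSE))

  merge_kind <- function(items) {
    o <- order(vapply(items, `[[`, 0, "start"))
    items <- items[o]
    merged <- list()
    cur <- items[[1]]; cur$seeds <- list(cur$seed)
    for (it in items[-1]) {
      if (it$start < cur$end) {  # overlap (half-open)
        cur$end <- max(cur$end, it$end)
        if (it$probability < cur$probability) {
          cur$probability <- it$probability; cur$span_n <- it$span_n
        }
        cur$seeds <- c(cur$seeds, list(it$seed))
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- it; cur$seeds <- list(cur$seed)
      }
    }
    merged[[length(merged) + 1L]] <- cur
    merged
  }

  out <- list()
  for (kind in c("trio", "duo")) {
    items <- Filter(function(x) x$kind == kind, cand)
    if (length(items) == 0L) next
    merged <- merge_kind(items)
    # extend, clip, and merge again
    for (i in seq_along(merged)) {
      merged[[i]]$start <- max(0L, merged[[i]]$start - as.integer(extension))
      merged[[i]]$end <- min(L, merged[[i]]$end + as.integer(extension))
      merged[[i]]$seed <- NULL
    }
    remerged <- list()
    cur <- merged[[1]]
    for (it in merged[-1]) {
      if (it$start < cur$end) {
        cur$end <- max(cur$end, it$end)
        if (it$probability < cur$probability) {
          cur$probability <- it$probability; cur$span_n <- it$span_n
        }
        cur$seeds <- c(cur$seeds, it$seeds)
      } else {
        remerged[[length(remerged) + 1L]] <- cur
        cur <- it
      }
    }
    remerged[[length(remerged) + 1L]] <- cur
    out <- c(out, remerged)
  }

  data.frame(col_start = vapply(out, `[[`, 0, "start"),
             col_end = vapply(out, `[[`, 0, "end"),
             kind = vapply(out, `[[`, "", "kind"),
             span_n = as.integer(vapply(out, `[[`, 0, "span_n")),
             probability = vapply(out, `[[`, 0, "probability"),
             seeds = I(lapply(out, `[[`, "seeds")),
             stringsAsFactors = FALSE)
}
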