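# Alignment containers and I/O: AXT / MAF / aligned pair-FASTA / BED readers,
# the inversion report TSV, and column <-> genome coordinate bookkeeping.
#
# Conventions: internal coordinates are 0-based half-open on the strand frame
# recorded in the interval; AXT (1-based inclusive) and MAF (0-based
# start/size) are converted at the boundary.  Alignment columns are likewise
# 0-based.

ALN_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Genomic interval
#'
#' A 0-based, half-open interval on one strand of a chromosome.
#'
#' @param chrom chromosome / sequence name.
#' @param start,end 0-based half-open bounds, \code{0 <= start <= end}.
#' @param strand \code{"+"} or \code{"-"}.  For \code{"-"} the coordinates are
#'   understood in the reverse-strand frame (AXT convention for reverse-strand
#'   targets).
#' @return an object of class \code{genomic_interval}.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start > end)
    stop("invalid interval: need 0 <= start <= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

ungapped_length <- function(text) nchar(gsub("-", "", text, fixed = TRUE))

#' Gapped pairwise alignment
#'
#' One local pairwise alignment: two equal-length gapped texts plus the genome
#' coordinates of each ungapped sequence.  This is the unit scanned for
#' ultramicro inversions.
#'
#' @param text_a,text_b gapped nucleotide strings over A,C,G,T,N,-; equal
#'   length, no column may be a gap in both.
#' @param loc_a,loc_b \code{\link{genomic_interval}}s of the ungapped
#'   sequences; defaults are synthetic intervals starting at 0.
#' @param id alignment identifier.
#' @return an object of class \code{gapped_pair}.
#' @export
gapped_pair <- function(text_a, text_b, loc_a = NULL, loc_b = NULL,
                        id = "pair") {
  stopifnot(is.character(text_a), is.character(text_b),
            length(text_a) == 1L, length(text_b) == 1L)
  text_a <- toupper(text_a); text_b <- toupper(text_b)
  if (nchar(text_a) != nchar(text_b))
    stop("text_a and text_b must have equal (gapped) length")
  ca <- charvec(text_a); cb <- charvec(text_b)
  bad <- !(ca %in% ALN_CHARS) | !(cb %in% ALN_CHARS)
  if (any(bad))
    stop("invalid character in alignment text at column ",
         which(bad)[1] - 1L)
  if (any(ca == "-" & cb == "-"))
    stop("column gapped in both sequences")
  if (is.null(loc_a)) loc_a <- genomic_interval(id, 0L, ungapped_length(text_a))
  if (is.null(loc_b)) loc_b <- genomic_interval(id, 0L, ungapped_length(text_b))
  if (interval_width(loc_a) != ungapped_length(text_a))
    stop("loc_a width does not match ungapped length of text_a")
  if (interval_width(loc_b) != ungapped_length(text_b))
    stop("loc_b width does not match ungapped length of text_b")
  structure(list(text_a = text_a, text_b = text_b,
                 loc_a = loc_a, loc_b = loc_b, id = as.character(id)),
            class = "gapped_pair")
}

#' @export
print.gapped_pair <- function(x, ...) {
  cat(sprintf("<gapped_pair '%s'> %d columns\n  a: %s:%d-%d(%s)\n  b: %s:%d-%d(%s)\n",
              x$id, nchar(x$text_a),
              x$loc_a$chrom, x$loc_a$start, x$loc_a$end, x$loc_a$strand,
              x$loc_b$chrom, x$loc_b$start, x$loc_b$end, x$loc_b$strand))
  invisible(x)
}

charvec <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Multiple alignment of three or more species
#'
#' @param names species labels.
#' @param rows equal-length gapped strings, one per species.
#' @return an object of class \code{multiple_alignment}.
#' @export
multiple_alignment <- function(names, rows) {
  stopifnot(length(names) == length(rows), length(rows) >= 2L)
  rows <- unname(toupper(unlist(rows)))
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("all rows must have equal length")
  structure(list(names = as.character(names), rows = rows,
                 column_count = L),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d rows x %d columns: %s\n",
              length(x$rows), x$column_count,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

read_lines_any <- function(con) {
  if (is.character(con) && length(con) == 1L && !grepl("\n", con))
    readLines(con, warn = FALSE)
  else if (inherits(con, "connection"))
    readLines(con, warn = FALSE)
  else
    stop("expected a file path or connection")
}

#' Read AXT alignments
#'
#' Parses UCSC AXT blocks into \code{\link{gapped_pair}}s.  AXT coordinates
#' (1-based inclusive) are converted to 0-based half-open; reverse-strand
#' target coordinates are kept in the reverse-strand frame per the AXT
#' convention, with the strand recorded.
#'
#' @param con file path or connection.
#' @return list of \code{\link{gapped_pair}}.
#' @export
read_axt <- function(con) {
  lines <- read_lines_any(con)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines)) | c(TRUE, rep(FALSE, max(0, length(lines) - 1)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("malformed AXT: number of non-empty lines not a multiple of 3")
  out <- vector("list", length(lines) %/% 3L)
  for (k in seq_along(out)) {
    hdr <- strsplit(trimws(lines[3L * k - 2L]), "\\s+")[[1]]
    if (length(hdr) < 9L)
      stop("malformed AXT header in block ", k)
    sa <- toupper(lines[3L * k - 1L]); sb <- toupper(lines[3L * k])
    if (nchar(sa) != nchar(sb))
      stop("malformed AXT block ", k, ": sequence length mismatch")
    loc_a <- genomic_interval(hdr[2], as.integer(hdr[3]) - 1L,
                              as.integer(hdr[4]), "+")
    loc_b <- genomic_interval(hdr[5], as.integer(hdr[6]) - 1L,
                              as.integer(hdr[7]), hdr[8])
    if (interval_width(loc_a) != ungapped_length(sa) ||
        interval_width(loc_b) != ungapped_length(sb))
      stop("malformed AXT block ", k,
           ": header span does not match ungapped sequence length")
    out[[k]] <- gapped_pair(sa, sb, loc_a, loc_b, id = hdr[1])
  }
  out
}

#' Write AXT alignments
#'
#' Inverse of \code{\link{read_axt}}.
#'
#' @param pairs list of \code{\link{gapped_pair}}.
#' @param path output file path.
#' @export
write_axt <- function(pairs, path) {
  if (inherits(pairs, "gapped_pair")) pairs <- list(pairs)
  lines <- character(0)
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    lines <- c(lines,
               paste(p$id, p$loc_a$chrom, p$loc_a$start + 1L, p$loc_a$end,
                     p$loc_b$chrom, p$loc_b$start + 1L, p$loc_b$end,
                     p$loc_b$strand, 0L),
               p$text_a, p$text_b, "")
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read MAF alignments
#'
#' Two-species blocks become \code{\link{gapped_pair}}s; blocks with three or
#' more rows become \code{\link{multiple_alignment}}s.  Reverse-strand rows
#' are kept in the given orientation with the source size recorded as an
#' attribute.
#'
#' @param con file path or connection.
#' @return list of \code{gapped_pair} / \code{multiple_alignment}.
#' @export
read_maf <- function(con) {
  lines <- read_lines_any(con)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list(); cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur$texts) > 0L) blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines) {
    if (grepl("^a", ln)) {
      blocks <- flush(cur, blocks)
      cur <- list(srcs = character(0), starts = integer(0), sizes = integer(0),
                  strands = character(0), src_sizes = integer(0),
                  texts = character(0))
    } else if (grepl("^s\\s", ln)) {
      if (is.null(cur)) stop("malformed MAF: 's' line outside a block")
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7L) stop("malformed MAF 's' line")
      cur$srcs <- c(cur$srcs, f[2])
      cur$starts <- c(cur$starts, as.integer(f[3]))
      cur$sizes <- c(cur$sizes, as.integer(f[4]))
      cur$strands <- c(cur$strands, f[5])
      cur$src_sizes <- c(cur$src_sizes, as.integer(f[6]))
      cur$texts <- c(cur$texts, toupper(f[7]))
    }
  }
  blocks <- flush(cur, blocks)
  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (length(unique(nchar(b$texts))) != 1L)
      stop("malformed MAF block ", k, ": row lengths differ")
    if (length(b$texts) == 2L) {
      locs <- lapply(1:2, function(i)
        genomic_interval(b$srcs[i], b$starts[i], b$starts[i] + b$sizes[i],
                         b$strands[i]))
      gp <- gapped_pair(b$texts[1], b$texts[2], locs[[1]], locs[[2]],
                        id = paste0("maf", k))
      attr(gp, "src_sizes") <- setNames(b$src_sizes, b$srcs)
      out[[k]] <- gp
    } else {
      ma <- multiple_alignment(b$srcs, b$texts)
      attr(ma, "src_sizes") <- setNames(b$src_sizes, b$srcs)
      out[[k]] <- ma
    }
  }
  out
}

#' Read an aligned two-record FASTA as a gapped pair
#'
#' Carrier for simulator and external aligner output: exactly two records of
#' equal gapped length.  Lowercase is uppercased; coordinates are synthetic
#' (chrom = record id, start 0).
#'
#' @param con file path.
#' @return a \code{\link{gapped_pair}}.
#' @export
read_pair_fasta <- function(con) {
  recs <- parse_fasta(read_lines_any(con))
  if (length(recs) != 2L)
    stop("expected exactly 2 FASTA records, got ", length(recs))
  if (nchar(recs[[1]]) != nchar(recs[[2]]))
    stop("aligned FASTA records have unequal lengths")
  gapped_pair(recs[[1]], recs[[2]],
              loc_a = genomic_interval(names(recs)[1], 0L,
                                       ungapped_length(toupper(recs[[1]]))),
              loc_b = genomic_interval(names(recs)[2], 0L,
                                       ungapped_length(toupper(recs[[2]]))),
              id = paste(names(recs), collapse = "|"))
}

parse_fasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records found")
  ends <- c(hdr[-1] - 1L, length(lines))
  recs <- lapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  })
  names(recs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  recs
}

#' Write a gapped pair as aligned FASTA
#'
#' @param pair a \code{\link{gapped_pair}}.
#' @param path output file path.
#' @export
write_pair_fasta <- function(pair, path) {
  writeLines(c(paste0(">", pair$loc_a$chrom), pair$text_a,
               paste0(">", pair$loc_b$chrom), pair$text_b), path)
  invisible(NULL)
}

#' Read a BED3+ file
#'
#' @param con file path or connection.
#' @param sort sort by (chrom, start)?
#' @return data frame with columns chrom, start, end, strand (0-based,
#'   half-open).
#' @export
read_bed <- function(con, sort = FALSE) {
  lines <- read_lines_any(con)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\\s+")
  chrom <- vapply(f, `[`, "", 1L)
  start <- as.integer(vapply(f, `[`, "", 2L))
  end <- as.integer(vapply(f, `[`, "", 3L))
  strand <- vapply(f, function(x) if (length(x) >= 6L) x[6] else "+", "")
  if (any(is.na(start) | is.na(end)) || any(start > end))
    stop("malformed BED: need 0 <= start <= end")
  out <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  if (sort) out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-pair coordinate maps: for each alignment column (0-based) the 0-based
# genome offset within loc (NA at gap columns), plus cumulative non-gap counts.
column_maps <- function(pair) {
  ca <- charvec(pair$text_a); cb <- charvec(pair$text_b)
  ga <- ca == "-"; gb <- cb == "-"
  a_off <- cumsum(!ga) - 1L; a_off[ga] <- NA_integer_
  b_off <- cumsum(!gb) - 1L; b_off[gb] <- NA_integer_
  list(a = a_off, b = b_off, gap_a = ga, gap_b = gb)
}

#' Map an alignment column to a genome position
#'
#' @param pair a \code{\link{gapped_pair}}.
#' @param column 0-based alignment column (vectorised).
#' @param which \code{"a"} or \code{"b"}.
#' @return integer genome positions (0-based, in the interval's strand frame),
#'   or \code{NA} where that row has a gap.
#' @export
column_to_genome <- function(pair, column, which = c("a", "b")) {
  which <- match.arg(which)
  L <- nchar(pair$text_a)
  if (any(column < 0L | column >= L)) stop("column out of range")
  maps <- column_maps(pair)
  off <- maps[[which]][column + 1L]
  loc <- if (which == "a") pair$loc_a else pair$loc_b
  loc$start + off
}

#' Map a genome position to its alignment column
#'
#' Inverse of \code{\link{column_to_genome}} on non-gap columns.
#'
#' @param pair a \code{\link{gapped_pair}}.
#' @param pos 0-based genome position (vectorised).
#' @param which \code{"a"} or \code{"b"}.
#' @return 0-based alignment columns.
#' @export
genome_to_column <- function(pair, pos, which = c("a", "b")) {
  which <- match.arg(which)
  loc <- if (which == "a") pair$loc_a else pair$loc_b
  if (any(pos < loc$start | pos >= loc$end)) stop("position out of range")
  maps <- column_maps(pair)
  off <- maps[[which]]
  cols <- which(!is.na(off))
  cols[match(pos - loc$start, off[cols])] - 1L
}

INVERSION_TSV_COLS <- c("id", "chromA", "startA", "endA", "chromB", "startB",
                        "endB", "length_bp", "criterion",
                        "similarity_inverted", "similarity_forward",
                        "at_exclusive", "lineage")

empty_calls <- function() {
  data.frame(id = character(0), chrom_a = character(0), start_a = integer(0),
             end_a = integer(0), chrom_b = character(0), start_b = integer(0),
             end_b = integer(0), length_bp = integer(0),
             criterion = character(0), similarity_inverted = numeric(0),
             similarity_forward = numeric(0), at_exclusive = logical(0),
             lineage = character(0), seg_a = character(0),
             seg_b = character(0), stringsAsFactors = FALSE)
}

#' Write the inversion report TSV
#'
#' One row per call, ordered by (chromA, startA).  Columns: id, chromA,
#' startA, endA, chromB, startB, endB, length_bp, criterion,
#' similarity_inverted, similarity_forward, at_exclusive, lineage.
#'
#' @param calls a calls data frame as returned by \code{\link{scan_pair}}.
#' @param path output file path.
#' @export
write_inversion_tsv <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0L) calls <- empty_calls()
  ord <- order(calls$chrom_a, calls$start_a)
  out <- data.frame(id = calls$id, chromA = calls$chrom_a,
                    startA = calls$start_a, endA = calls$end_a,
                    chromB = calls$chrom_b, startB = calls$start_b,
                    endB = calls$end_b, length_bp = calls$length_bp,
                    criterion = calls$criterion,
                    similarity_inverted = calls$similarity_inverted,
                    similarity_forward = calls$similarity_forward,
                    at_exclusive = as.integer(calls$at_exclusive),
                    lineage = ifelse(is.na(calls$lineage), "NA", calls$lineage),
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read an inversion report TSV
#'
#' @param con file path.
#' @return calls data frame (internal column names).
#' @export
read_inversion_tsv <- function(con) {
  tab <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(id = "character", chromA = "character",
                                   chromB = "character",
                                   criterion = "character",
                                   lineage = "character"))
  if (!all(INVERSION_TSV_COLS %in% names(tab)))
    stop("missing columns in inversion TSV")
  data.frame(id = tab$id, chrom_a = tab$chromA, start_a = tab$startA,
             end_a = tab$endA, chrom_b = tab$chromB, start_b = tab$startB,
             end_b = tab$endB, length_bp = tab$length_bp,
             criterion = tab$criterion,
             similarity_inverted = tab$similarity_inverted,
             similarity_forward = tab$similarity_forward,
             at_exclusive = tab$at_exclusive != 0L,
             lineage = ifelse(tab$lineage == "NA", NA_character_,
                              tab$lineage),
             stringsAsFactors = FALSE)
}
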