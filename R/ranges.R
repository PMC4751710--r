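## genomic_ranges module: interval model, positional-input parsing, and
## identifier-kind auto-detection.
##
## Intervals are carried as GRanges. The external convention for numeric
## (start, end) pairs in this package's API is BED-style 0-based half-open;
## GRanges is 1-based closed internally, so genomic_interval() converts.

#' Build a GRanges from 0-based half-open coordinates
#'
#' The universal interval constructor: strand-aware half-open ranges on a
#' named chromosome, with an optional free-text label stored in
#' `mcols(x)$label`.
#'
#' @param chrom chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval (`"."` = unstranded).
#' @param label free-text names (may be empty strings).
#' @return a [GenomicRanges::GRanges] with a `label` metadata column.
#' @examples
#' genomic_interval("chr1", 100, 200)
#' @export
genomic_interval <- function(chrom, start, end, strand = ".", label = "") {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  label <- rep_len(as.character(label), n)
  if (any(is.na(start) | is.na(end))) stop_input("interval coordinates must be numeric")
  if (any(start < 0)) stop_input("interval start must be >= 0")
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    stop_input(sprintf("invalid interval %s:%d-%d (start >= end)", chrom[i], start[i], end[i]))
  }
  if (any(!nzchar(chrom))) stop_input("chromosome name must be non-empty")
  if (!all(strand %in% c("+", "-", "."))) stop_input("strand must be one of '+', '-', '.'")
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), strand = strand)
  S4Vectors::mcols(gr)$label <- label
  gr
}

## 0-based accessors (inverse of the constructor's conversion).
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)
interval_label <- function(gr) {
  lab <- S4Vectors::mcols(gr)$label
  if (is.null(lab)) rep("", length(gr)) else as.character(lab)
}
## floor((start0 + end0) / 2), the anchor used by profiles and nearest_gene
interval_center <- function(gr) floor((start0(gr) + end0(gr)) / 2)

#' Query set: labelled intervals plus unresolved input tokens
#'
#' @param label set name (unique within one run).
#' @param ranges a `GRanges` of member intervals.
#' @param unresolved character vector of input tokens that could not be mapped.
#' @return an object of class `query_set`.
#' @export
query_set <- function(label, ranges, unresolved = character(0)) {
  stopifnot(is.character(label), length(label) == 1L, methods::is(ranges, "GRanges"))
  structure(list(label = label, ranges = ranges, unresolved = unresolved),
            class = "query_set")
}

#' @export
print.query_set <- function(x, ...) {
  cat(sprintf("<query_set '%s': %d intervals, %d unresolved tokens>\n",
              x$label, length(x$ranges), length(x$unresolved)))
  invisible(x)
}

#' @export
length.query_set <- function(x) length(x$ranges)

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

drop_blank <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  lines[!grepl("^(#|track |browser )", lines)]
}

#' Parse BED lines into intervals
#'
#' Accepts BED3 through BED6; column 4 becomes the label, column 6 the strand
#' (defaulting to `"."`). Coordinates follow the BED convention, 0-based
#' half-open.
#'
#' @param lines character vector of BED lines (comments and blank lines are
#'   ignored).
#' @return a `GRanges` with one interval per line.
#' @export
parse_bed <- function(lines) {
  lines <- drop_blank(lines)
  if (length(lines) == 0L) stop_input("no ranges parsed: empty BED input")
  fields <- lapply(lines, split_fields)
  parse_one <- function(f, i) {
    if (length(f) < 3L) stop_input(sprintf("BED line %d: fewer than 3 fields", i))
    s <- suppressWarnings(as.numeric(gsub(",", "", f[2])))
    e <- suppressWarnings(as.numeric(gsub(",", "", f[3])))
    if (is.na(s) || is.na(e)) stop_input(sprintf("BED line %d: non-integer coordinates", i))
    if (s >= e) stop_input(sprintf("BED line %d: start >= end (%s >= %s)", i, f[2], f[3]))
    list(chrom = f[1], start = s, end = e,
         label = if (length(f) >= 4L) f[4] else "",
         strand = if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else ".")
  }
  recs <- mapply(parse_one, fields, seq_along(fields), SIMPLIFY = FALSE)
  genomic_interval(chrom = vapply(recs, `[[`, "", "chrom"),
                   start = vapply(recs, `[[`, 0, "start"),
                   end = vapply(recs, `[[`, 0, "end"),
                   strand = vapply(recs, `[[`, "", "strand"),
                   label = vapply(recs, `[[`, "", "label"))
}

#' Write intervals as BED6 text
#'
#' The inverse of [parse_bed()] (audit output for resolved query and
#' background sets). Score column is 0; `"."` strand for unstranded.
#'
#' @param gr a `GRanges`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return the BED lines, invisibly when written to `path`.
#' @export
write_bed <- function(gr, path = NULL) {
  strand_chr <- as.character(GenomicRanges::strand(gr))
  strand_chr[strand_chr == "*"] <- "."
  lab <- interval_label(gr)
  lab[!nzchar(lab)] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(GenomeInfoDb::seqnames(gr)),
                   start0(gr), end0(gr), lab, strand_chr)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

coord_regex <- "^([^:[:space:]]+):([0-9,]+)-([0-9,]+)$"

#' Parse a genome-browser coordinate token
#'
#' `"chr:start-end"` text is read as 1-based inclusive (the genome-browser
#' convention) and converted to the package's 0-based half-open intervals;
#' commas in numbers are allowed.
#'
#' @param token a single coordinate string, e.g. `"chr1:1,000-2,000"`.
#' @return a length-1 `GRanges`.
#' @examples
#' parse_coordinate("chr1:1000-2000")  # 0-based [999, 2000)
#' @export
parse_coordinate <- function(token) {
  token <- trimws(token)
  m <- regmatches(token, regexec(coord_regex, token))[[1]]
  if (length(m) != 4L) stop_input(sprintf("malformed coordinate token '%s'", token))
  s1 <- as.numeric(gsub(",", "", m[3]))
  e1 <- as.numeric(gsub(",", "", m[4]))
  if (e1 < s1) stop_input(sprintf("coordinate '%s': end < start", token))
  genomic_interval(m[2], s1 - 1, e1)
}

#' Format an interval as 1-based inclusive coordinate text
#'
#' @param gr a `GRanges`.
#' @return character vector, one `"chrom:start-end"` token per interval.
#' @export
format_coordinate <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(gr)),
          start0(gr) + 1L, end0(gr))
}

#' Parse ENCODE narrowPeak lines
#'
#' narrowPeak is BED6+4: the interval columns follow [parse_bed()] and
#' column 7 (`signalValue`, the peak enrichment magnitude) is attached as a
#' metadata column, along with the integer display `score` (column 5).
#'
#' @param lines character vector of narrowPeak lines.
#' @return a `GRanges` with `label`, `score` and `signal_value` metadata
#'   columns, in input order.
#' @export
parse_narrowpeak <- function(lines) {
  lines <- drop_blank(lines)
  if (length(lines) == 0L) stop_input("no ranges parsed: empty narrowPeak input")
  fields <- lapply(lines, split_fields)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 7L)) {
    stop_input(sprintf("narrowPeak line %d: fewer than 7 columns", which(nf < 7L)[1L]))
  }
  gr <- parse_bed(lines)
  sig <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
  if (any(is.na(sig))) {
    stop_input(sprintf("narrowPeak line %d: non-numeric signalValue",
                       which(is.na(sig))[1L]))
  }
  if (any(sig < 0)) stop_input("narrowPeak signalValue must be >= 0")
  S4Vectors::mcols(gr)$score <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  S4Vectors::mcols(gr)$signal_value <- sig
  gr
}

#' Filter peaks by signal value
#'
#' Keeps peaks with `signal_value` strictly greater than `min_signal`, then
#' optionally the `top_n` strongest (or `bottom_n` weakest, for background
#' construction) by signal value, ties broken by input order.
#'
#' @param peaks a `GRanges` from [parse_narrowpeak()] (requires a
#'   `signal_value` metadata column).
#' @param min_signal keep peaks with signal strictly above this (default
#'   `-Inf`, keep all).
#' @param top_n optional count of highest-signal peaks to retain.
#' @param bottom_n optional count of lowest-signal peaks to retain (mutually
#'   exclusive with `top_n`).
#' @return the filtered `GRanges`.
#' @export
filter_peaks <- function(peaks, min_signal = -Inf, top_n = NULL, bottom_n = NULL) {
  if (length(peaks) == 0L) stop_input("filter_peaks: empty peak input")
  sig <- S4Vectors::mcols(peaks)$signal_value
  if (is.null(sig)) stop_input("filter_peaks: peaks lack a signal_value column")
  if (!is.null(top_n) && !is.null(bottom_n)) {
    stop_input("filter_peaks: give top_n or bottom_n, not both")
  }
  keep <- peaks[sig > min_signal]
  sig <- S4Vectors::mcols(keep)$signal_value
  if (!is.null(top_n)) {
    ord <- order(-sig)  # stable: ties stay in input order
    keep <- keep[sort(head(ord, top_n))]
  } else if (!is.null(bottom_n)) {
    ord <- order(sig)
    keep <- keep[sort(head(ord, bottom_n))]
  }
  if (length(keep) == 0L) stop_input("no peaks survive filter")
  keep
}

classify_token <- function(token) {
  nf <- length(split_fields(token))
  f <- split_fields(token)
  num <- function(i) !is.na(suppressWarnings(as.numeric(gsub(",", "", f[i]))))
  if (nf >= 7L && num(2) && num(3) && num(7)) return("narrowpeak")
  if (nf >= 3L && num(2) && num(3)) return("bed")
  if (grepl(coord_regex, trimws(token))) return("coordinate")
  if (grepl("^ENS[A-Z]*T[0-9]+(\\.[0-9]+)?$", trimws(token))) return("ensembl_transcript")
  if (grepl("^(NM|NR|XM|XR)_[0-9]+(\\.[0-9]+)?$", trimws(token))) return("refseq")
  "symbol"
}

#' Auto-detect the kind of a positional or identifier input
#'
#' Classifies each token by pattern -- narrowPeak (>= 7 tab fields, numeric
#' columns 2, 3 and 7), BED (>= 3 fields, numeric columns 2 and 3),
#' `chrom:start-end` coordinates, Ensembl transcript IDs (`ENST`/`ENSMUST`
#' prefixes, optionally versioned), RefSeq accessions (`NM_`/`NR_`/`XM_`/
#' `XR_`), or gene symbols as fallback -- and returns the majority kind.
#' Minority tokens are reported in the `minority` attribute (they end up in a
#' query set's `unresolved` slot) with a warning rather than an error.
#'
#' @param tokens character vector of input lines/tokens.
#' @return a single kind string, one of `"bed"`, `"narrowpeak"`,
#'   `"coordinate"`, `"ensembl_transcript"`, `"refseq"`, `"symbol"`, with
#'   attribute `minority` holding off-kind tokens.
#' @export
detect_input_kind <- function(tokens) {
  tokens <- drop_blank(tokens)
  if (length(tokens) == 0L) stop_input("detect_input_kind: empty input")
  kinds <- vapply(tokens, classify_token, "", USE.NAMES = FALSE)
  tab <- sort(table(kinds), decreasing = TRUE)
  majority <- names(tab)[which.max(tab)]  # ties: most frequent, then table order
  minority <- tokens[kinds != majority]
  if (length(minority) > 0L) {
    warning(sprintf("mixed input kinds: %d token(s) not of majority kind '%s'",
                    length(minority), majority))
  }
  structure(majority, minority = minority)
}
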