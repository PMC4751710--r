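## track_store module: bigWig registry and the coverage-extraction primitive
## that every statistic in the package is built on.

#' Load a track collection from a metadata table
#'
#' Reads a tab-separated metadata table describing a set of bigWig coverage
#' tracks and validates it: track IDs must be unique, every file must exist
#' and open as bigWig, and all tracks must share one genome assembly.
#' Relative `path` entries are resolved against the table's own directory,
#' so a fixture directory is self-contained.
#'
#' @param metadata_path TSV with columns `track_id`, `path`, `assembly`,
#'   `category`, `description` and optional `total_tags` (total aligned tags
#'   for per-million scaling).
#' @return an object of class `track_collection`: the validated data.frame
#'   with an `assembly` attribute.
#' @export
load_collection <- function(metadata_path) {
  if (!file.exists(metadata_path)) stop_io("track metadata not found: ", metadata_path)
  md <- utils::read.delim(metadata_path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("track_id", "path", "assembly", "category", "description")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0L) {
    stop_input("track metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"total_tags" %in% names(md)) md$total_tags <- NA_real_
  md$total_tags <- suppressWarnings(as.numeric(md$total_tags))
  if (nrow(md) == 0L) stop_input("track metadata is empty")
  dup <- md$track_id[duplicated(md$track_id)]
  if (length(dup) > 0L) stop_input("duplicate track_id: ", paste(unique(dup), collapse = ", "))
  base_dir <- dirname(normalizePath(metadata_path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", md$path), md$path, file.path(base_dir, md$path))
  for (p in abs) {
    if (!file.exists(p)) stop_io("bigWig file not found: ", p)
  }
  md$path <- abs
  for (p in abs) {
    ok <- tryCatch({ rtracklayer::BigWigFile(p); TRUE }, error = function(e) FALSE)
    if (!ok) stop_io("file does not open as bigWig: ", p)
  }
  if (length(unique(md$assembly)) > 1L) {
    stop_input("tracks disagree on assembly: ", paste(unique(md$assembly), collapse = ", "))
  }
  structure(md, class = c("track_collection", "data.frame"),
            assembly = md$assembly[1L])
}

#' @export
print.track_collection <- function(x, ...) {
  cat(sprintf("<track_collection: %d tracks, assembly %s>\n",
              nrow(x), attr(x, "assembly")))
  print.data.frame(utils::head(as.data.frame(x)[c("track_id", "category", "description")], 10))
  invisible(x)
}

track_path <- function(track) {
  if (is.character(track) && length(track) == 1L) return(track)
  if (is.list(track) || is.data.frame(track)) return(as.character(track$path)[1L])
  stop_input("cannot interpret track argument")
}

## Map requested chromosome names onto the names present in one bigWig file,
## trying user aliases then the ubiquitous "chr1" <-> "1" convention.
## Returns a character vector with NA where no name matches.
map_chrom_names <- function(chroms, file_chroms, aliases = NULL) {
  out <- ifelse(chroms %in% file_chroms, chroms, NA_character_)
  miss <- which(is.na(out))
  for (i in miss) {
    cand <- c(unname(aliases[chroms[i]]),
              sub("^chr", "", chroms[i]),
              paste0("chr", chroms[i]))
    cand <- cand[!is.na(cand) & cand %in% file_chroms]
    if (length(cand) > 0L) out[i] <- cand[1L]
  }
  out
}

## Vectorized core: length-normalized mean coverage of each interval in one
## bigWig. Missing data counts as 0; intervals are clamped to the recorded
## chromosome length for reading but divided by the full requested width.
## Chromosomes absent from the file yield 0 with one warning per chromosome.
track_interval_means <- function(path, gr, aliases = NULL) {
  bwf <- rtracklayer::BigWigFile(path)
  sl <- GenomeInfoDb::seqlengths(bwf)
  req_chrom <- as.character(GenomeInfoDb::seqnames(gr))
  file_chrom <- map_chrom_names(req_chrom, names(sl), aliases)
  widths <- GenomicRanges::width(gr)
  sums <- numeric(length(gr))

  for (ch in unique(req_chrom[is.na(file_chrom)])) {
    warning(sprintf("chromosome '%s' absent from %s; coverage counted as 0",
                    ch, basename(path)))
  }
  present <- !is.na(file_chrom)
  if (any(present)) {
    s <- GenomicRanges::start(gr)[present]
    e <- GenomicRanges::end(gr)[present]
    ch <- file_chrom[present]
    e_cl <- pmin(e, sl[ch])
    s_cl <- pmax(s, 1L)
    ok <- s_cl <= e_cl  # intervals entirely off-chromosome contribute 0
    if (any(ok)) {
      which_gr <- GenomicRanges::GRanges(ch[ok], IRanges::IRanges(s_cl[ok], e_cl[ok]))
      cov <- rtracklayer::import.bw(bwf, which = which_gr, as = "RleList")
      idx <- which(present)[ok]
      for (c2 in unique(ch[ok])) {
        j <- ch[ok] == c2
        v <- IRanges::Views(cov[[c2]], IRanges::IRanges(s_cl[ok][j], e_cl[ok][j]))
        sums[idx[j]] <- IRanges::viewSums(v)
      }
    }
  }
  sums / widths
}

#' Mean per-base coverage of one interval in one track
#'
#' The package's length normalization: the sum of per-base signal over the
#' half-open interval divided by the interval length. Bases without data in
#' the bigWig count as 0 (no reads means zero signal); portions of the
#' interval beyond the recorded chromosome length also contribute 0 while
#' the divisor stays the full requested length, keeping promoter windows
#' comparable near chromosome ends. A chromosome entirely absent from the
#' file yields 0 with a warning (files from different sources disagree on
#' `"chr1"` versus `"1"` naming; both spellings are tried automatically,
#' plus any `aliases` given).
#'
#' @param track a `track_collection` row, a list with a `path` element, or a
#'   bigWig file path.
#' @param interval a `GRanges` (each range is measured independently).
#' @param aliases optional named character vector mapping requested
#'   chromosome names to the file's names.
#' @return numeric vector of mean coverages, one per range.
#' @export
mean_coverage <- function(track, interval, aliases = NULL) {
  if (length(interval) == 0L) stop_input("mean_coverage: empty interval input")
  track_interval_means(track_path(track), interval, aliases)
}

#' Coverage matrix of a collection over a set of intervals
#'
#' Entry (t, i) is [mean_coverage()] of track t over interval i. Evaluation
#' is track-major so each bigWig is opened once. Per-track read errors are
#' downgraded to warnings (the failing track's row is 0), never aborting the
#' whole matrix.
#'
#' @param collection a [load_collection()] result.
#' @param intervals a non-empty `GRanges`.
#' @param aliases optional chromosome-name aliases (see [mean_coverage()]).
#' @return numeric matrix, tracks x intervals, with `track_id` rownames and
#'   interval labels (or coordinates) as colnames.
#' @export
coverage_matrix <- function(collection, intervals, aliases = NULL) {
  if (length(intervals) == 0L) stop_input("coverage_matrix: empty interval list")
  if (nrow(collection) == 0L) stop_input("coverage_matrix: empty collection")
  labs <- interval_label(intervals)
  labs[!nzchar(labs)] <- format_coordinate(intervals)[!nzchar(labs)]
  m <- matrix(0, nrow = nrow(collection), ncol = length(intervals),
              dimnames = list(collection$track_id, labs))
  for (t in seq_len(nrow(collection))) {
    m[t, ] <- tryCatch(
      track_interval_means(collection$path[t], intervals, aliases),
      error = function(e) {
        warning(sprintf("track %s failed (%s); row set to 0",
                        collection$track_id[t], conditionMessage(e)))
        numeric(length(intervals))
      })
  }
  m
}

#' Scale a coverage value to tags per million
#'
#' Display normalization used for cross-track profile comparison:
#' `value * 1e6 / total_tags`. It is not applied in the enrichment test,
#' where a track-constant factor shifts the log coverages of query and
#' background equally and cancels from the t statistic.
#'
#' @param value coverage value(s).
#' @param total_tags total aligned tags of the track; `NA` returns the value
#'   unchanged with a warning (track assumed pre-normalized).
#' @return scaled value(s).
#' @export
scale_to_tags_per_million <- function(value, total_tags) {
  if (is.null(total_tags) || length(total_tags) == 0L || is.na(total_tags)) {
    warning("total_tags absent; assuming track is pre-normalized")
    return(value)
  }
  if (total_tags <= 0) stop_input("total_tags must be positive")
  value * 1e6 / total_tags
}
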