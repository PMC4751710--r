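## profiles module: center-anchored average coverage ("Histogram") and
## per-interval coverage distributions ("Stack plot"), strand-aware so the
## x-axis reads 5' -> 3'.

## Per-base values of one window [s0, e0) (0-based) from a coverage RleList,
## zero-padded outside [0, chrom_len).
window_values <- function(rle, chrom_len, s0, e0) {
  out <- numeric(e0 - s0)
  lo <- max(s0, 0); hi <- min(e0, chrom_len)
  if (lo < hi) {
    out[(lo - s0 + 1):(hi - s0)] <- as.numeric(rle[(lo + 1):hi])
  }
  out
}

#' Center-anchored average coverage profile
#'
#' For each interval of each set, reads the per-base signal in the window
#' `[center - halfwidth, center + halfwidth)` around the interval center
#' (`floor((start + end)/2)`; for promoter windows built as TSS +/- w this is
#' the TSS). Windows of `-` strand intervals are reversed so offsets run in
#' transcription direction, 5' to 3'; `.`/`*` intervals are treated as `+`
#' (peaks are unstranded). Per-base columns are averaged across the set's
#' intervals, then binned by averaging within consecutive `bin_size` bins.
#' Positions outside chromosome bounds contribute 0.
#'
#' @param track a `track_collection` row, list with `path` (and optionally
#'   `total_tags`), or a bigWig path.
#' @param sets a list of [query_set()]s (a single set is accepted).
#' @param halfwidth window half-width in bp (default 1000, i.e. a 2000 bp
#'   window around the center).
#' @param bin_size bp per bin (default 10); must divide `2 * halfwidth`.
#' @param scale_per_million if `TRUE`, scale by the track's `total_tags` to
#'   tags per million (display normalization).
#' @param aliases optional chromosome-name aliases.
#' @return object of class `profile_matrix`: list with `offsets` (bin start
#'   offsets relative to the center, 5'->3'), `values` (sets x positions
#'   matrix of mean coverage), `bin_size`, `n_intervals`, `track_id`.
#' @export
coverage_profile <- function(track, sets, halfwidth = 1000, bin_size = 10,
                             scale_per_million = FALSE, aliases = NULL) {
  if (methods::is(sets, "query_set")) sets <- list(sets)
  stopifnot(halfwidth > 0, bin_size >= 1)
  if ((2 * halfwidth) %% bin_size != 0) {
    stop_input("bin_size must divide the window width 2*halfwidth")
  }
  if (any(vapply(sets, function(s) length(s$ranges) == 0L, NA))) {
    stop_input("coverage_profile: empty query set")
  }
  path <- track_path(track)
  bwf <- rtracklayer::BigWigFile(path)
  sl <- GenomeInfoDb::seqlengths(bwf)
  width <- 2 * halfwidth

  ## one read covering every window of every set
  all_gr <- do.call(c, lapply(sets, function(s) s$ranges))
  centers <- interval_center(all_gr)
  req_chrom <- as.character(GenomeInfoDb::seqnames(all_gr))
  file_chrom <- map_chrom_names(req_chrom, names(sl), aliases)
  s_cl <- pmax(centers - halfwidth, 0) + 1
  e_cl <- pmin(centers + halfwidth, ifelse(is.na(file_chrom), 0, sl[file_chrom]))
  ok <- !is.na(file_chrom) & s_cl <= e_cl
  cov <- if (any(ok)) {
    rtracklayer::import.bw(bwf, which = GenomicRanges::GRanges(
      file_chrom[ok], IRanges::IRanges(s_cl[ok], e_cl[ok])), as = "RleList")
  } else NULL
  if (!all(ok)) {
    warning(sprintf("%d window(s) with no readable coverage contribute zeros", sum(!ok)))
  }

  idx0 <- 0L
  profiles <- matrix(0, nrow = length(sets), ncol = width,
                     dimnames = list(vapply(sets, `[[`, "", "label"), NULL))
  for (si in seq_along(sets)) {
    gr <- sets[[si]]$ranges
    acc <- numeric(width)
    for (i in seq_along(gr)) {
      k <- idx0 + i
      v <- if (ok[k]) {
        window_values(cov[[file_chrom[k]]], sl[file_chrom[k]],
                      centers[k] - halfwidth, centers[k] + halfwidth)
      } else numeric(width)
      if (as.character(GenomicRanges::strand(gr[i])) == "-") v <- rev(v)
      acc <- acc + v
    }
    profiles[si, ] <- acc / length(gr)
    idx0 <- idx0 + length(gr)
  }
  if (scale_per_million) {
    tt <- if (is.list(track) || is.data.frame(track)) track$total_tags[1] else NA
    profiles <- scale_to_tags_per_million(profiles, tt)
  }
  if (bin_size > 1) {
    nb <- width / bin_size
    profiles <- t(apply(profiles, 1, function(r) {
      colMeans(matrix(r, nrow = bin_size, ncol = nb))
    }))
  }
  structure(list(offsets = seq(-halfwidth, halfwidth - 1, by = bin_size),
                 values = profiles, bin_size = bin_size,
                 n_intervals = vapply(sets, function(s) length(s$ranges), 0L),
                 track_id = if (is.list(track) || is.data.frame(track))
                   as.character(track$track_id)[1] else basename(path)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix: %d set(s) x %d positions, bin %d bp, track %s>\n",
              nrow(x$values), ncol(x$values), x$bin_size, x$track_id))
  invisible(x)
}

#' Write a profile matrix as TSV
#'
#' Columns: `offset` then one column of mean coverage per query set.
#'
#' @param pm a [coverage_profile()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(pm, path) {
  df <- data.frame(offset = pm$offsets, t(pm$values), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-interval coverage distributions for one track ("stack plot" data)
#'
#' For each query set, the per-interval mean coverages of the track sorted
#' in descending order -- the ranked display behind the stacked
#' distribution plots.
#'
#' @param track as in [coverage_profile()].
#' @param sets list of [query_set()]s (single set accepted).
#' @param aliases optional chromosome-name aliases.
#' @return object of class `stack_data`: list with `track_id` and `sets`, a
#'   named list of sorted coverage vectors (names are interval labels).
#' @export
stack_data <- function(track, sets, aliases = NULL) {
  if (methods::is(sets, "query_set")) sets <- list(sets)
  if (any(vapply(sets, function(s) length(s$ranges) == 0L, NA))) {
    stop_input("stack_data: empty query set")
  }
  path <- track_path(track)
  out <- lapply(sets, function(s) {
    v <- track_interval_means(path, s$ranges, aliases)
    names(v) <- interval_label(s$ranges)
    sort(v, decreasing = TRUE)
  })
  names(out) <- vapply(sets, `[[`, "", "label")
  structure(list(track_id = if (is.list(track) || is.data.frame(track))
                   as.character(track$track_id)[1] else basename(path),
                 sets = out),
            class = "stack_data")
}

#' Write stack data as TSV
#'
#' Long format: `set`, `rank`, `label`, `coverage`.
#'
#' @param sd a [stack_data()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(sd, path) {
  rows <- do.call(rbind, lapply(names(sd$sets), function(nm) {
    v <- sd$sets[[nm]]
    data.frame(set = nm, rank = seq_along(v),
               label = names(v) %||% rep("", length(v)),
               coverage = as.numeric(v), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
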