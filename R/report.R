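## report module: the ranked enrichment table in the canonical column
## layout, per-interval gene annotation, and the reproducibility manifest.

#' Nearest gene to an interval
#'
#' Finds, per interval, the gene whose canonical TSS minimizes the distance
#' to the interval center; ties (within 1 bp parity) break lexicographically
#' on the gene symbol. The reported distance is 0 when the center lies
#' within `window` bp of the TSS (i.e. inside the gene's promoter window).
#'
#' @param interval a `GRanges`.
#' @param index an [load_annotation()] index.
#' @param window promoter half-window for the distance-0 rule (default 1000).
#' @return data.frame with `gene_symbol` and `distance` per interval;
#'   chromosomes without genes give an empty symbol with a warning.
#' @export
nearest_gene <- function(interval, index, window = 1000) {
  genes <- index$genes
  centers <- interval_center(interval)
  chroms <- as.character(GenomeInfoDb::seqnames(interval))
  sym <- character(length(interval))
  dist <- rep(NA_real_, length(interval))
  for (i in seq_along(interval)) {
    g <- genes[genes$chrom == chroms[i], , drop = FALSE]
    if (nrow(g) == 0L) {
      warning(sprintf("no genes on chromosome %s", chroms[i]))
      next
    }
    d <- abs(g$tss - centers[i])
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[order(g$gene_symbol[best])][1L]
    sym[i] <- g$gene_symbol[best]
    dist[i] <- if (d[best] <= window) 0 else d[best]
  }
  data.frame(gene_symbol = sym, distance = dist, stringsAsFactors = FALSE)
}

#' Format p-values for report display
#'
#' Two significant digits in scientific notation below 0.001, four decimals
#' otherwise (the table's mixed notation: `6.7e-06` next to `0.0093`).
#'
#' @param p numeric p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001,
         formatC(p, format = "e", digits = 1),
         formatC(p, format = "f", digits = 4))
}

#' Write the ranked enrichment report as TSV
#'
#' Columns in the canonical output order: track, query and background mean
#' coverage, fold difference, p-value, Bonferroni-corrected p-value, then
#' file-path columns standing in for the embedded stack/histogram plots,
#' the per-interval gene annotation, and the track description. Row order
#' is the enrichment ranking. P-values are formatted by [format_pvalue()];
#' numeric columns keep full precision.
#'
#' @param table an [enrich_all()] result.
#' @param path output TSV path.
#' @param collection optional [load_collection()] result supplying the
#'   `description` column.
#' @param genes optional named character vector (track-independent): the
#'   per-interval `label=symbol:coverage` summary placed in the `genes`
#'   column of every row, as produced by [summarize_query_genes()].
#' @param artifacts optional data.frame with columns `track_id`,
#'   `stack_path`, `profile_path`.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, collection = NULL, genes = NULL,
                         artifacts = NULL) {
  n <- nrow(table)
  df <- data.frame(
    track = table$track_id,
    query = table$query_mean,
    background = table$background_mean,
    fold = table$fold_difference,
    p = format_pvalue(table$p_value),
    bonferroni = format_pvalue(table$bonferroni_p),
    p_raw = table$p_value,
    bonferroni_raw = table$bonferroni_p,
    stack = rep("", n), histogram = rep("", n),
    genes = rep(if (is.null(genes)) "" else paste(genes, collapse = ";"), n),
    description = rep("", n),
    stringsAsFactors = FALSE
  )
  if (!is.null(collection)) {
    df$description <- collection$description[match(df$track, collection$track_id)]
  }
  if (!is.null(artifacts)) {
    i <- match(df$track, artifacts$track_id)
    df$stack <- ifelse(is.na(i), "", artifacts$stack_path[i])
    df$histogram <- ifelse(is.na(i), "", artifacts$profile_path[i])
  }
  con <- tryCatch(file(path, "w"), error = function(e) stop_io("cannot write ", path))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize query intervals as label=gene:coverage triples
#'
#' Builds the per-interval content of the report's `genes` column: each
#' query interval's label, nearest gene symbol, and mean coverage in a
#' reference track (typically the top-ranked one).
#'
#' @param query a [query_set()].
#' @param index an [load_annotation()] index.
#' @param coverages numeric vector of per-interval coverages (same order),
#'   or `NULL` to omit.
#' @return character vector, one `label=symbol:coverage` entry per interval.
#' @export
summarize_query_genes <- function(query, index, coverages = NULL) {
  ng <- nearest_gene(query$ranges, index)
  lab <- interval_label(query$ranges)
  lab[!nzchar(lab)] <- format_coordinate(query$ranges)[!nzchar(lab)]
  if (is.null(coverages)) {
    sprintf("%s=%s", lab, ng$gene_symbol)
  } else {
    sprintf("%s=%s:%.4g", lab, ng$gene_symbol, coverages)
  }
}

#' Read back a report written by [write_report()]
#'
#' @param path TSV path.
#' @return data.frame with raw numeric columns restored.
#' @export
read_report <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(p = "character", bonferroni = "character"))
}

#' Write the run manifest (JSON sidecar)
#'
#' Records everything needed to reproduce a run bit-for-bit: the
#' configuration, the seed, the number of tests m, the background mode, and
#' md5 digests of the input files.
#'
#' @param path output JSON path.
#' @param config an [enrichment_config()].
#' @param m number of tracks tested.
#' @param background_mode `"sampled"` or `"user-defined"`.
#' @param inputs named character vector of input file paths to digest.
#' @param extra optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, m, background_mode,
                           inputs = character(0), extra = list()) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(unname(inputs)))
  } else list()
  manifest <- c(list(config = unclass(config), m = m,
                     background = background_mode,
                     input_md5 = digests), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
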