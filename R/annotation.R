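## annotation module: GTF indexing, identifier -> promoter resolution, and
## background promoter sampling.

#' Load and index a genome annotation
#'
#' Reads transcript features from a GTF (Ensembl/GENCODE dialects, via
#' rtracklayer) together with a UCSC-style `chrom.sizes` table, and builds
#' the lookup index used for identifier resolution, promoter construction
#' and background sampling.
#'
#' The transcription start site (TSS) is stored 0-based: the feature start
#' for `+` strand transcripts, the feature end minus one for `-` strand.
#' The canonical transcript of a gene is the one whose TSS is 5'-most in
#' transcription direction (smallest TSS on `+`, largest on `-`), a
#' deterministic rule that is stable across annotation releases.
#'
#' @param gtf_path path to a GTF file with `transcript` features carrying
#'   `gene_name` (or `gene_id`) and `transcript_id` attributes; an optional
#'   `refseq_id` attribute (comma-separated) adds RefSeq lookup keys.
#' @param chrom_sizes_path path to a two-column `<chrom> <length>` text file
#'   covering every chromosome used by the transcripts.
#' @return an object of class `annotation_index` with elements
#'   `transcripts` (data.frame: transcript_id, gene_symbol, refseq_ids,
#'   chrom, strand, tss), `genes` (canonical transcript per gene symbol) and
#'   `chrom_sizes` (named numeric).
#' @export
load_annotation <- function(gtf_path, chrom_sizes_path) {
  if (!file.exists(gtf_path)) stop_io("annotation GTF not found: ", gtf_path)
  if (!file.exists(chrom_sizes_path)) stop_io("chrom.sizes not found: ", chrom_sizes_path)
  sizes_df <- utils::read.delim(chrom_sizes_path, header = FALSE,
                                col.names = c("chrom", "size"),
                                colClasses = c("character", "numeric"))
  chrom_sizes <- stats::setNames(sizes_df$size, sizes_df$chrom)

  gtf <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                  error = function(e) {
                    stop_input("no transcript features readable from GTF: ", gtf_path)
                  })
  tx <- gtf[!is.na(gtf$type) & as.character(gtf$type) == "transcript"]
  if (length(tx) == 0L) stop_input("no transcript features in GTF: ", gtf_path)

  tx_id <- as.character(tx$transcript_id)
  sym <- as.character(tx$gene_name %||% tx$gene_id)
  sym[is.na(sym) | !nzchar(sym)] <- NA_character_
  bad <- is.na(tx_id) | is.na(sym)
  if (any(bad)) {
    warning(sprintf("skipping %d transcript(s) lacking transcript_id/gene_name", sum(bad)))
    tx <- tx[!bad]; tx_id <- tx_id[!bad]; sym <- sym[!bad]
  }
  if (length(tx) == 0L) stop_input("zero usable transcripts loaded")

  strand_chr <- as.character(GenomicRanges::strand(tx))
  if (!all(strand_chr %in% c("+", "-"))) {
    keep <- strand_chr %in% c("+", "-")
    warning(sprintf("skipping %d unstranded transcript(s)", sum(!keep)))
    tx <- tx[keep]; tx_id <- tx_id[keep]; sym <- sym[keep]
    strand_chr <- strand_chr[keep]
  }
  tss <- ifelse(strand_chr == "+",
                GenomicRanges::start(tx) - 1L,
                GenomicRanges::end(tx) - 1L)
  refseq <- if (!is.null(tx$refseq_id)) as.character(tx$refseq_id) else rep(NA_character_, length(tx))

  transcripts <- data.frame(
    transcript_id = sub("\\.[0-9]+$", "", tx_id),
    gene_symbol = sym,
    refseq_ids = ifelse(is.na(refseq), "", refseq),
    chrom = as.character(GenomeInfoDb::seqnames(tx)),
    strand = strand_chr,
    tss = as.numeric(tss),
    stringsAsFactors = FALSE
  )
  missing_chrom <- setdiff(unique(transcripts$chrom), names(chrom_sizes))
  if (length(missing_chrom) > 0L) {
    stop_input("chrom.sizes lacks chromosome(s): ", paste(missing_chrom, collapse = ", "))
  }
  if (any(transcripts$tss >= chrom_sizes[transcripts$chrom])) {
    stop_input("transcript TSS beyond chromosome length; annotation/sizes mismatch")
  }

  ## canonical transcript: 5'-most TSS in transcription direction, with the
  ## transcript_id as a deterministic tie-break
  key <- ifelse(transcripts$strand == "+", transcripts$tss, -transcripts$tss)
  ord <- order(transcripts$gene_symbol, key, transcripts$transcript_id)
  genes <- transcripts[ord, ][!duplicated(transcripts$gene_symbol[ord]), ]
  genes <- genes[order(genes$gene_symbol), ]
  rownames(genes) <- NULL

  structure(list(transcripts = transcripts, genes = genes, chrom_sizes = chrom_sizes),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("<annotation_index: %d transcripts, %d genes, %d chromosomes>\n",
              nrow(x$transcripts), nrow(x$genes), length(x$chrom_sizes)))
  invisible(x)
}

## Resolve one vector of identifier tokens of a known kind to transcript rows.
## Returns list(rows = data.frame subset, unresolved = character).
resolve_tokens <- function(tokens, index, kind) {
  tokens <- trimws(tokens)
  tx <- index$transcripts
  hit_rows <- integer(0)
  unresolved <- character(0)
  for (tok in tokens) {
    rows <- switch(kind,
      ensembl_transcript = which(tx$transcript_id == sub("\\.[0-9]+$", "", tok)),
      refseq = {
        acc <- sub("\\.[0-9]+$", "", tok)
        which(vapply(strsplit(tx$refseq_ids, ","), function(r) acc %in% sub("\\.[0-9]+$", "", r), NA))
      },
      symbol = {
        exact <- which(tx$gene_symbol == tok)
        if (length(exact) > 0L) exact else which(tolower(tx$gene_symbol) == tolower(tok))
      },
      stop_input("unknown identifier kind: ", kind))
    if (length(rows) == 0L) unresolved <- c(unresolved, tok) else hit_rows <- c(hit_rows, rows[1L])
  }
  list(rows = tx[hit_rows, , drop = FALSE], unresolved = unresolved)
}

## Promoter window around a 0-based TSS, in transcription direction.
## + strand: [tss - up, tss + down); - strand: [tss - down + 1, tss + up + 1).
promoter_window <- function(tss, strand, upstream, downstream, chrom_len) {
  s <- ifelse(strand == "+", tss - upstream, tss - downstream + 1)
  e <- ifelse(strand == "+", tss + downstream, tss + upstream + 1)
  s <- pmax(s, 0)
  e <- pmin(e, chrom_len)
  cbind(start = s, end = e)
}

#' Resolve identifiers to promoter windows
#'
#' Maps gene symbols, Ensembl transcript IDs or RefSeq accessions (kind
#' auto-detected unless given) to strand-aware promoter intervals
#' `[TSS - upstream, TSS + downstream)` measured in transcription direction
#' and clamped to chromosome bounds. Version suffixes on IDs are stripped;
#' symbol matching is case-insensitive with exact match preferred. Tokens
#' that cannot be mapped are collected in the result's `unresolved` slot
#' with a warning, not an error, unless nothing resolves.
#'
#' @param tokens character vector of identifiers.
#' @param index an [load_annotation()] index.
#' @param upstream,downstream window extents in bp (defaults 1000/1000,
#'   i.e. a 2 kb window centered on the TSS).
#' @param label name for the resulting set.
#' @param kind identifier kind; `NULL` (default) auto-detects via
#'   [detect_input_kind()].
#' @return a [query_set()] whose intervals carry the transcript strand and
#'   the input token as label.
#' @export
promoters_for <- function(tokens, index, upstream = 1000, downstream = 1000,
                          label = "query", kind = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  if (upstream + downstream <= 0) stop_input("promoter window must have positive width")
  tokens <- trimws(tokens[nzchar(trimws(tokens))])
  if (length(tokens) == 0L) stop_input("no identifier tokens given")
  if (is.null(kind)) kind <- as.character(suppressWarnings(detect_input_kind(tokens)))
  res <- resolve_tokens(tokens, index, kind)
  if (nrow(res$rows) == 0L) stop_input("zero tokens resolved against the annotation")
  if (length(res$unresolved) > 0L) {
    warning(sprintf("%d token(s) unresolved: %s", length(res$unresolved),
                    paste(utils::head(res$unresolved, 5), collapse = ", ")))
  }
  rows <- res$rows
  w <- promoter_window(rows$tss, rows$strand, upstream, downstream,
                       index$chrom_sizes[rows$chrom])
  resolved_tokens <- setdiff(tokens, res$unresolved)
  gr <- genomic_interval(rows$chrom, w[, "start"], w[, "end"],
                         strand = rows$strand, label = resolved_tokens)
  query_set(label, gr, unresolved = res$unresolved)
}

#' Sample a background set of random gene promoters
#'
#' Draws `n` distinct genes uniformly without replacement with a seeded
#' generator and returns one promoter per gene via its canonical transcript,
#' using the same window as the query. The default `n = 1000` random gene
#' promoters is the standard reference against which query coverage is
#' tested; any user-defined set may replace it. The draw depends only on the
#' sorted gene symbols, so it is invariant to transcript order in the GTF.
#'
#' @param index an [load_annotation()] index.
#' @param n number of genes to draw (default 1000).
#' @param seed integer seed for the draw.
#' @param exclude optional [query_set()]; genes whose symbol appears among
#'   its interval labels (or symbols resolving to them) are never drawn.
#' @param upstream,downstream promoter window in bp (defaults 1000/1000).
#' @param label set name (default `"background"`).
#' @return a [query_set()] of `n` promoter intervals.
#' @export
sample_background <- function(index, n = 1000, seed = 1L, exclude = NULL,
                              upstream = 1000, downstream = 1000,
                              label = "background") {
  stopifnot(is_count(n), n >= 1)
  genes <- index$genes
  if (!is.null(exclude)) {
    drop_syms <- unique(c(interval_label(exclude$ranges), exclude$unresolved))
    genes <- genes[!(genes$gene_symbol %in% drop_syms), , drop = FALSE]
  }
  genes <- genes[order(genes$gene_symbol), , drop = FALSE]
  if (nrow(genes) < n) {
    stop_input(sprintf("only %d eligible genes; choose n <= %d", nrow(genes), nrow(genes)))
  }
  idx <- with_seed(seed, sample.int(nrow(genes), n))
  rows <- genes[idx, , drop = FALSE]
  w <- promoter_window(rows$tss, rows$strand, upstream, downstream,
                       index$chrom_sizes[rows$chrom])
  gr <- genomic_interval(rows$chrom, w[, "start"], w[, "end"],
                         strand = rows$strand, label = rows$gene_symbol)
  query_set(label, gr)
}
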