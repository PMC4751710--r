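## synthetic module: fixture generator. Produces a toy genome annotation and
## bigWig track collections with planted enrichment so every other module is
## testable with no external download.
##
## Signal model per base: baseline + |N(0, noise_sd)| (half-normal noise
## keeps coverage non-negative); enriched tracks add a triangular peak of
## height peak_amplitude and half-width w centered on each enriched gene's
## TSS. The triangle (not a Gaussian) is chosen so planted means have an
## exact closed form: its per-base sum is amplitude * w exactly.

#' Synthetic fixture configuration
#'
#' Defaults describe the standard small world: 1 chromosome of 1 Mb, 100
#' evenly spaced genes with alternating strands, 20 tracks of which 1 is
#' enriched with peaks of amplitude 3x the noise SD at 24 genes -- the scale
#' of a small promoter query against a modest track catalogue, sized so a
#' full generation-plus-analysis round trip stays fast.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes total genes, distributed evenly across chromosomes.
#' @param enriched_genes count of genes carrying planted peaks (chosen
#'   deterministically, evenly spread through the gene list) or an explicit
#'   character vector of gene symbols.
#' @param peak_amplitude planted peak height (coverage units).
#' @param peak_halfwidth planted peak half-width (bp); the peak spans
#'   `2*peak_halfwidth - 1` bases around the TSS.
#' @param noise_sd half-normal noise scale (coverage units).
#' @param baseline constant background coverage.
#' @param n_tracks tracks in the collection.
#' @param n_enriched_tracks how many tracks carry the planted peaks.
#' @param noise_bin resolution of the noise in bp: 1 (default) draws one
#'   value per base; larger values draw one value per `noise_bin`-bp bin
#'   (piecewise-constant noise), trading per-base granularity for much
#'   faster bigWig writing in large simulation studies. Peaks are always
#'   per-base.
#' @param seed master seed; all per-track seeds derive from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chroms = 1, chrom_length = 1e6, n_genes = 100,
                             enriched_genes = 24, peak_amplitude = 3,
                             peak_halfwidth = 250, noise_sd = 1, baseline = 0.5,
                             n_tracks = 20, n_enriched_tracks = 1,
                             noise_bin = 1, seed = 42L) {
  stopifnot(is_count(n_chroms), n_chroms >= 1, chrom_length >= 1,
            is_count(n_genes), n_genes >= 1,
            peak_amplitude >= 0, peak_halfwidth >= 1,
            noise_sd >= 0, baseline >= 0,
            is_count(n_tracks), n_tracks >= 1,
            is_count(n_enriched_tracks), n_enriched_tracks >= 0,
            n_enriched_tracks <= n_tracks,
            is_count(noise_bin), noise_bin >= 1)
  if (is.numeric(enriched_genes) && enriched_genes > n_genes) {
    stop_input("enriched_genes exceeds n_genes")
  }
  structure(list(n_chroms = n_chroms, chrom_length = chrom_length,
                 n_genes = n_genes, enriched_genes = enriched_genes,
                 peak_amplitude = peak_amplitude, peak_halfwidth = peak_halfwidth,
                 noise_sd = noise_sd, baseline = baseline,
                 n_tracks = n_tracks, n_enriched_tracks = n_enriched_tracks,
                 noise_bin = noise_bin, seed = as.integer(seed)),
            class = "synthetic_config")
}

GENE_BODY <- 600L       # synthetic gene length (bp)
MIN_SPACING <- 1200L    # keeps gene bodies and GTF coordinates on-chromosome

## Deterministic layout: gene i of a chromosome sits at
## tss = spacing * (i - 1/2), strands alternating +,-,+,...
synthetic_layout <- function(config) {
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  counts <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  layout <- do.call(rbind, lapply(seq_len(config$n_chroms), function(ci) {
    k <- counts[ci]
    if (k == 0L) return(NULL)
    spacing <- floor(config$chrom_length / k)
    if (spacing < MIN_SPACING) {
      stop_input(sprintf(
        "genome too small: %d genes on a %g bp chromosome gives spacing %d < %d",
        k, config$chrom_length, spacing, MIN_SPACING))
    }
    i <- seq_len(k)
    data.frame(chrom = sprintf("chr%d", ci),
               gene_symbol = "",   # filled below, globally numbered
               tss = floor(spacing * (i - 0.5)),
               strand = ifelse(i %% 2 == 1L, "+", "-"),
               stringsAsFactors = FALSE)
  }))
  layout$gene_symbol <- sprintf("SYNG%04d", seq_len(nrow(layout)))
  layout$transcript_id <- sprintf("ENST%011d", seq_len(nrow(layout)))
  layout$refseq_id <- sprintf("NM_%06d", seq_len(nrow(layout)))
  layout
}

enriched_symbols <- function(config, layout) {
  eg <- config$enriched_genes
  if (is.character(eg)) {
    missing <- setdiff(eg, layout$gene_symbol)
    if (length(missing) > 0L) stop_input("unknown enriched gene(s): ",
                                         paste(missing, collapse = ", "))
    return(eg)
  }
  if (eg == 0) return(character(0))
  layout$gene_symbol[unique(round(seq(1, nrow(layout), length.out = eg)))]
}

#' Generate the synthetic genome annotation
#'
#' Writes a GTF (gene/transcript/exon features with `gene_id`, `gene_name`,
#' `transcript_id` and `refseq_id` attributes) and a `chrom.sizes` file for
#' the evenly spaced, strand-alternating toy gene layout. The output loads
#' cleanly with [load_annotation()].
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return list with `gtf`, `chrom_sizes` (paths) and `layout` (data.frame).
#' @export
make_annotation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- synthetic_layout(config)

  ## 1-based GTF coordinates of the gene body around each 0-based TSS
  start1 <- ifelse(layout$strand == "+", layout$tss + 1L, layout$tss + 2L - GENE_BODY)
  end1 <- ifelse(layout$strand == "+", layout$tss + GENE_BODY, layout$tss + 1L)
  attrs <- sprintf(
    'gene_id "%s"; gene_name "%s"; transcript_id "%s"; refseq_id "%s";',
    layout$gene_symbol, layout$gene_symbol, layout$transcript_id, layout$refseq_id)
  feature_line <- function(type) {
    sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
            layout$chrom, type, start1, end1, layout$strand, attrs)
  }
  gtf_path <- file.path(dir, "annotation.gtf")
  writeLines(as.vector(rbind(feature_line("gene"), feature_line("transcript"),
                             feature_line("exon"))), gtf_path)
  sizes_path <- file.path(dir, "chrom.sizes")
  writeLines(sprintf("chr%d\t%d", seq_len(config$n_chroms),
                     as.integer(config$chrom_length)), sizes_path)
  list(gtf = gtf_path, chrom_sizes = sizes_path, layout = layout)
}

## Triangular peak heights at integer offsets -(w-1)..(w-1) from the TSS.
triangle_values <- function(amplitude, halfwidth) {
  d <- seq.int(-(halfwidth - 1L), halfwidth - 1L)
  amplitude * (1 - abs(d) / halfwidth)
}

#' Generate one synthetic bigWig track
#'
#' Per-base signal is `baseline + |N(0, noise_sd)|` across every chromosome
#' (at `noise_bin` resolution); when `enriched`, a triangular peak of height
#' `peak_amplitude` and half-width `peak_halfwidth` is added per-base at
#' each enriched gene's TSS. Identical `(config, seed)` reproduce identical
#' coverage values.
#'
#' @param config a [synthetic_config()].
#' @param layout gene layout from [make_annotation()].
#' @param enriched logical: plant peaks?
#' @param seed seed for this track's noise.
#' @param path output bigWig path.
#' @return `path`, invisibly, with attribute `total_signal` (the genome-wide
#'   signal sum, the synthetic stand-in for total aligned tags).
#' @export
make_track <- function(config, layout, enriched, seed, path) {
  L <- as.integer(config$chrom_length)
  bin <- config$noise_bin
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  esym <- enriched_symbols(config, layout)
  rles <- with_seed(seed, {
    lapply(seq_along(chroms), function(ci) {
      if (config$noise_sd > 0) {
        nbins <- ceiling(L / bin)
        draws <- config$baseline + abs(stats::rnorm(nbins, 0, config$noise_sd))
        lens <- rep.int(bin, nbins)
        lens[nbins] <- L - bin * (nbins - 1L)
        rle <- S4Vectors::Rle(draws, lens)
      } else {
        rle <- S4Vectors::Rle(config$baseline, L)
      }
      if (enriched && config$peak_amplitude > 0) {
        g <- layout[layout$chrom == chroms[ci] & layout$gene_symbol %in% esym, ]
        if (nrow(g) > 0L) {
          ## sparse peak signal assembled as one Rle, added in a single pass
          w <- config$peak_halfwidth
          tri <- triangle_values(config$peak_amplitude, w)
          vals <- numeric(0); lens <- integer(0)
          pos <- 0L  # 0-based cursor
          for (tss in sort(g$tss)) {
            lo <- max(tss - w + 1L, 0L); hi <- min(tss + w - 1L, L - 1L)
            keep <- tri[(lo - (tss - w + 1L) + 1L):(length(tri) - ((tss + w - 1L) - hi))]
            if (lo > pos) { vals <- c(vals, 0); lens <- c(lens, lo - pos) }
            vals <- c(vals, keep); lens <- c(lens, rep.int(1L, length(keep)))
            pos <- hi + 1L
          }
          if (pos < L) { vals <- c(vals, 0); lens <- c(lens, L - pos) }
          rle <- rle + S4Vectors::Rle(vals, lens)
        }
      }
      rle
    })
  })
  cov <- methods::as(stats::setNames(rles, chroms), "SimpleRleList")
  rtracklayer::export.bw(cov, path)
  invisible(structure(path,
                      total_signal = sum(vapply(rles, function(r) sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r)), 0))))
}

#' Generate a complete synthetic track collection
#'
#' Writes the annotation, `n_tracks` bigWig files (the first
#' `n_enriched_tracks` carry the planted peaks), the track metadata TSV and
#' a ground-truth JSON into `dir`. Per-track seeds derive deterministically
#' from the master seed, so identical `(config, seed)` produce identical
#' directories.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return list with `collection` (a validated [load_collection()] result),
#'   `annotation` (a [load_annotation()] index), `truth` (enriched track
#'   ids, enriched gene symbols, amplitude, seed), and `paths`.
#' @export
make_collection <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- make_annotation(config, dir)
  esym <- enriched_symbols(config, ann$layout)

  track_ids <- sprintf("SYNT_%02d", seq_len(config$n_tracks))
  enriched <- seq_len(config$n_tracks) <= config$n_enriched_tracks
  paths <- file.path(dir, paste0(track_ids, ".bw"))
  total_tags <- numeric(config$n_tracks)
  for (t in seq_len(config$n_tracks)) {
    p <- make_track(config, ann$layout, enriched[t], derive_seed(config$seed, t), paths[t])
    ## total signal stands in for "total aligned tags" in per-million scaling
    total_tags[t] <- round(attr(p, "total_signal"))
  }
  md_path <- file.path(dir, "tracks.tsv")
  utils::write.table(
    data.frame(track_id = track_ids, path = basename(paths), assembly = "syn1",
               category = ifelse(enriched, "TF", "other"),
               total_tags = total_tags,
               description = ifelse(enriched,
                                    "synthetic track with planted TSS peaks",
                                    "synthetic null track"),
               stringsAsFactors = FALSE),
    md_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(enriched_track_ids = track_ids[enriched],
                enriched_gene_symbols = esym,
                peak_amplitude = config$peak_amplitude,
                peak_halfwidth = config$peak_halfwidth,
                noise_sd = config$noise_sd, baseline = config$baseline,
                noise_bin = config$noise_bin, seed = config$seed)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(collection = load_collection(md_path),
       annotation = load_annotation(ann$gtf, ann$chrom_sizes),
       truth = truth,
       paths = list(dir = dir, gtf = ann$gtf, chrom_sizes = ann$chrom_sizes,
                    metadata = md_path, truth = truth_path, tracks = paths))
}
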