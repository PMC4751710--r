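## Shared fixtures, built in code at test time. The small synthetic
## collection is generated once per session and reused read-only.

fixture_env <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    dir <- file.path(tempdir(), "trackenrich-shared-fixture")
    cfg <- synthetic_config(n_genes = 50, chrom_length = 2e5, n_tracks = 4,
                            n_enriched_tracks = 1, enriched_genes = 10,
                            peak_amplitude = 3, peak_halfwidth = 100,
                            noise_sd = 1, baseline = 0.5, seed = 101L)
    fixture_env$cfg <- cfg
    fixture_env$fx <- make_collection(cfg, dir)
  }
  fixture_env
}

## Write an arbitrary per-base signal as bigWig; values is a numeric vector
## (or named list of vectors, one per chromosome).
write_bw <- function(values, path, chrom = "chr1") {
  if (!is.list(values)) values <- stats::setNames(list(values), chrom)
  rles <- lapply(values, function(v) if (methods::is(v, "Rle")) v else S4Vectors::Rle(v))
  rtracklayer::export.bw(methods::as(rles, "SimpleRleList"), path)
  path
}

constant_bw <- function(value, len, path, chrom = "chr1") {
  write_bw(stats::setNames(list(S4Vectors::Rle(value, len)), chrom), path)
}

## Independent per-base oracle for mean coverage: expands the bigWig's
## stored intervals (GRanges route, one full read) into plain per-base
## numeric vectors, missing bases = 0, divisor = full requested width.
## Deliberately a different code path from track_interval_means
## (which-restricted RleList + viewSums).
bruteforce_mean <- function(path, gr) {
  bwf <- rtracklayer::BigWigFile(path)
  sl <- GenomeInfoDb::seqlengths(bwf)
  dat <- rtracklayer::import.bw(bwf)          # every stored run, genome-wide
  dat_chrom <- as.character(GenomeInfoDb::seqnames(dat))
  vecs <- lapply(stats::setNames(nm = names(sl)), function(ch) {
    v <- numeric(sl[[ch]])
    d <- dat[dat_chrom == ch]
    if (length(d) > 0L) {
      pos <- sequence(GenomicRanges::width(d), from = GenomicRanges::start(d))
      v[pos] <- rep(d$score, GenomicRanges::width(d))
    }
    v
  })
  vapply(seq_along(gr), function(i) {
    chrom <- as.character(GenomeInfoDb::seqnames(gr[i]))
    if (!chrom %in% names(vecs)) return(0)
    s <- GenomicRanges::start(gr[i]); e <- GenomicRanges::end(gr[i])
    s_cl <- max(s, 1L); e_cl <- min(e, length(vecs[[chrom]]))
    if (s_cl > e_cl) return(0)
    sum(vecs[[chrom]][s_cl:e_cl]) / (e - s + 1L)
  }, 0)
}

## Tiny hand-written GTF + chrom.sizes for annotation tests.
## transcripts: data.frame(chrom, start1, end1, strand, gene, tx, refseq)
write_test_gtf <- function(transcripts, chrom_sizes, dir = tempfile("ann")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";%s',
                   transcripts$gene, transcripts$gene, transcripts$tx,
                   ifelse(is.na(transcripts$refseq), "",
                          sprintf(' refseq_id "%s";', transcripts$refseq)))
  lines <- sprintf("%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                   transcripts$chrom, transcripts$start1, transcripts$end1,
                   transcripts$strand, attrs)
  gtf <- file.path(dir, "test.gtf")
  writeLines(lines, gtf)
  sizes <- file.path(dir, "chrom.sizes")
  writeLines(sprintf("%s\t%d", names(chrom_sizes), as.integer(chrom_sizes)), sizes)
  list(gtf = gtf, chrom_sizes = sizes)
}

## Default toy annotation: two genes on chr1 (one with two transcripts to
## exercise the canonical rule), one minus-strand gene on chr2.
toy_annotation <- function() {
  tr <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start1 = c(5001, 3001, 20001, 6001),
    end1 = c(6000, 4000, 21000, 9001),
    strand = c("+", "+", "+", "-"),
    gene = c("Alpha", "Alpha", "Beta", "Gamma"),
    tx = c("ENST00000000001.2", "ENST00000000002", "ENST00000000003",
           "ENST00000000004"),
    refseq = c("NM_000001", "NM_000011", "NM_000002", NA),
    stringsAsFactors = FALSE
  )
  paths <- write_test_gtf(tr, c(chr1 = 50000, chr2 = 10000))
  load_annotation(paths$gtf, paths$chrom_sizes)
}
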