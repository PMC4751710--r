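# trackenrich

Rank collections of bigWig coverage tracks (ChIP-seq, CAGE, histone marks,
polymerases) by statistical over-representation of signal in a query set of
genomic ranges versus a background set — entirely locally, from the raw
per-base coverage.

**Who it is for.** Anyone holding (a) a list of co-expressed genes, novel
transcripts, or peaks from a new ChIP-seq experiment, and (b) a directory of
bigWig tracks with a metadata table, who wants to know *which tracks light
up over my regions* — to nominate shared transcription factors, chromatin
states, protein–protein interactions at peak sets, or cell-type-specific
expression. Because the unit of analysis is an arbitrary genomic interval,
the query is not limited to annotated promoters.

## The statistic

For track *T* and interval *i* of length *L<sub>i</sub>*, the observation is
the length-normalized mean coverage
*x<sub>i</sub>* = (1/*L<sub>i</sub>*) Σ<sub>b∈i</sub> *T*(b)
(bases absent from the bigWig count as 0). Per-interval means over the query
*Q* and background *B* (default: 1000 random gene promoters, seeded) are
log-transformed, *y<sub>i</sub>* = log₂(*x<sub>i</sub>* + 0.01), and compared
with a **Welch two-sample t-test**; per-track p-values are **Bonferroni**
corrected over the *m* tracks tested, min(1, *p·m*). The report also carries
the raw means, their fold difference, and strand-aware 5′→3′ coverage
profiles around interval centers. A parametric **z-score**
(*y* − mean<sub>B</sub>)/sd<sub>B</sub> serves single-region inspection.

## Worked example

No external data needed — the package fabricates a complete testbed (toy
genome, GTF, 20 bigWig tracks, one carrying planted TSS peaks of amplitude
3× the noise SD at 24 genes):

```r
library(trackenrich)

fixdir <- file.path(tempdir(), "demo")
cfg <- synthetic_config(seed = 42)            # 1 chrom x 1 Mb, 100 genes, 20 tracks
fx  <- make_collection(cfg, fixdir)

query      <- promoters_for(fx$truth$enriched_gene_symbols, fx$annotation)
background <- sample_background(fx$annotation, n = 50, seed = 1)
tab <- enrich_all(fx$collection, query, background)
head(as.data.frame(tab)[, c("track_id", "query_mean", "background_mean",
                            "fold_difference", "p_value", "bonferroni_p")], 5)
```

```
  track_id query_mean background_mean fold_difference  p_value bonferroni_p
1  SYNT_01       1.67            1.39           1.203 6.74e-17     1.35e-15
2  SYNT_04       1.30            1.30           1.004 2.60e-01     1.00e+00
3  SYNT_14       1.30            1.30           0.998 2.79e-01     1.00e+00
4  SYNT_15       1.30            1.30           1.002 3.28e-01     1.00e+00
5  SYNT_06       1.30            1.30           1.002 3.30e-01     1.00e+00
```

Reading this: the planted track `SYNT_01` ranks first — its mean coverage
over the 24 query promoters (1.67) exceeds the background mean (1.39, the
baseline plus half-normal noise), a 1.2-fold difference whose Welch test
p-value of 6.7e-17 survives Bonferroni correction over the 20 tracks tested
(1.35e-15 < 0.05). The 19 null tracks sit at fold ≈ 1 with uncorrected
p-values scattered uniformly — none significant.

Single-region inspection of the first query promoter:

```r
z <- single_region_zscore(fx$collection, query$ranges[1], background)
head(z[, c("track_id", "z", "p_value")], 3)
```

```
  track_id    z p_value
1  SYNT_01 1.77  0.0769
2  SYNT_06 1.60  0.1101
3  SYNT_10 1.59  0.1115
```

One 2 kb promoter is a single observation, so the planted track still tops
the list but without the decisive significance of the 24-promoter set —
exactly the power difference the two modes are meant to illustrate.

Profiles, stack data and reports:

```r
top <- fx$collection[fx$collection$track_id == tab$track_id[1], ]
pm  <- coverage_profile(top, list(query, background))   # 2000 bp, 10 bp bins, 5'->3'
write_profile(pm, "profile.tsv")
write_report(tab, "report.tsv", collection = fx$collection,
             genes = summarize_query_genes(query, fx$annotation))
```

## Command line

```sh
Rscript -e 'trackenrich::main()' simulate --out fixture --seed 42
Rscript -e 'trackenrich::main()' enrich \
    --annotation fixture/annotation.gtf --chrom-sizes fixture/chrom.sizes \
    --tracks fixture/tracks.tsv --query genes.txt \
    --background sample:1000 --seed 1 --out results/
Rscript -e 'trackenrich::main()' inspect --region "chr1:5000-7000" \
    --annotation fixture/annotation.gtf --chrom-sizes fixture/chrom.sizes \
    --tracks fixture/tracks.tsv --out results/
```

Query inputs are auto-detected: gene symbols, Ensembl transcript IDs,
RefSeq accessions (resolved to TSS ± 1000 bp promoter windows via the GTF),
BED, ENCODE narrowPeak, or `chr:start-end` coordinates. Each `--query`
repeat is one query set; `--background` takes a file in any of the same
formats or `sample:N`. Every run writes a JSON manifest (config, seed, *m*,
input digests) sufficient to reproduce it bit for bit.

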