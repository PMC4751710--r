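---
title: "Coverage-based track enrichment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based track enrichment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given a set of genomic regions that share a biological trait — promoters of
co-expressed genes, peaks from a new ChIP-seq experiment, any list of
coordinates — which of the signal tracks in a local collection (transcription
factor ChIP-seq, histone marks, polymerases, CAGE) shows systematically
elevated coverage over those regions? Classical over-representation tools
answer this with a hypergeometric test on pre-computed peak/promoter overlap
sets. `trackenrich` instead works directly on raw per-base coverage stored in
bigWig files, so the query is not restricted to annotated promoters: any
interval, including unannotated transcripts or intergenic peaks, is a valid
observation.

## The statistical model

For a track $T$ and an interval $i$ of length $L_i$, the observation is the
length-normalized mean coverage

$$x_i = \frac{1}{L_i}\sum_{b \in i} T(b),$$

with bases missing from the bigWig contributing 0 (no reads means zero
signal). Given a query set $Q$ and a background set $B$ (by default 1000
gene promoters sampled uniformly without replacement with a seeded
generator), the per-interval means are transformed as

$$y_i = \log_2(x_i + c), \qquad c = 0.01,$$

and the two samples $\{y_i\}_{i\in Q}$ and $\{y_i\}_{i\in B}$ are compared
with a Welch (unequal-variance) two-sample $t$-test. Per track the report
carries the raw query and background means, their ratio
$(\bar x_Q + c)/(\bar x_B + c)$ as the fold difference, the Welch $t$, its
Satterthwaite degrees of freedom, the two-sided $p$-value, and the
Bonferroni-corrected value $\min(1, p\,m)$ where $m$ is the number of tracks
actually tested in the run. Results are sorted by ascending $p$, ties broken
by descending fold difference, then track ID, so reports are deterministic.

For a single region, a parametric z-score replaces the $t$-test:
$z = (y_\text{region} - \bar y_B)/s_B$ on the log scale, with a two-sided
standard-normal tail probability.

### Assumptions and their limits

The $t$-test treats per-interval log mean coverages as approximately normal
i.i.d. samples. Each observation is itself an average over hundreds to
thousands of bases, so the central limit theorem does most of the work even
though raw coverage is skewed; the log transform removes the remaining
right tail. Observations are independent only if intervals do not overlap —
heavily overlapping query intervals (e.g. promoters of a tandem gene
cluster) share bases and inflate the effective sample size. Duplicated
intervals in a query set are deliberately kept (each contributes one
observation); deduplication would silently change the sample size.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| pseudocount $c$ | 0.01 | coverage | keeps $\log(0)$ finite while preserving contrast among sub-1 mean coverages typical of depth-normalized tracks |
| log base | 2 | — | provably irrelevant to $t$, $p$ and ranking (a base change rescales both samples by one constant); 2 is the field's habit |
| background size | 1000 | promoters | the standard reference: 1000 random gene promoters, replaceable by any user set |
| promoter window | 1000/1000 | bp up/downstream of the TSS | a 2 kb window centered on the TSS, matching the 2 kb profile width |
| profile half-width | 1000 | bp | "2000 bp around the center" read literally as total width 2000; the alternative reading (±2000) stays available via the argument |
| profile bin | 10 | bp | smooths per-base noise at 200 plot points; binning is exactly the average of the bin-size-1 profile |
| test sides | 2 | — | sidedness is a convention here; two-sided is conservative, direction is read off the fold difference |

Conventions the package had to pick because the problem statement leaves
them open: coordinate text `chr:start-end` is parsed as 1-based inclusive
(the genome-browser convention) and BED stays native 0-based half-open; the
canonical transcript of a gene is the one with the 5'-most TSS in
transcription direction (deterministic and stable across annotation
releases); version suffixes on transcript/RefSeq accessions are stripped;
symbol matching is case-insensitive with exact match preferred; mixed
identifier kinds in one input resolve by majority, with minority tokens
reported as unresolved rather than failing the submission; query genes are
*not* excluded from the default background (with 1000 draws the effect of a
few shared promoters is negligible) but an `exclude` argument documents and
removes the ambiguity.

### Per-million scaling is display-only

Coverage scaled to tags per million rescales a whole track by one positive
constant. With the pseudocount co-scaled, $\log$ of both samples shifts by
the same constant, which cancels exactly from the $t$ statistic — so
normalization state cannot change the ranking, and the package applies
per-million scaling only when drawing profiles. This is verified as a
property test (scale-cancellation).

## Numerical and degenerate-input choices

* Welch, not pooled Student: query and background routinely differ in size
  (24 vs 1000) and variance.
* Both variances zero and equal means: $t = 0$, $p = 1$. Both zero and
  different means: $p = 0$, flagged degenerate. Tracks identically zero on
  both sets are reported with $p = 1$ and a degenerate flag rather than
  dropped — dropping would silently change $m$ and hide data problems.
* Intervals clamped at chromosome ends keep the *full requested length* as
  divisor, so promoter windows near ends stay comparable.
* Chromosome naming (`chr1` vs `1`) is bridged automatically at read time,
  with a user-supplied alias table for anything less standard; a chromosome
  truly absent from a file contributes zero coverage with a warning, never
  an abort, because one mislabeled track should not kill a 400-track run.
* Interval centers are `floor((start+end)/2)` in 0-based coordinates; for a
  promoter window built as TSS±w this is exactly the TSS. Minus-strand
  profile windows are reversed per base so the x-axis reads 5'→3'. The
  promoter construction places the minus-strand window one base to the
  right (`[tss-down+1, tss+up+1)`), which exactly compensates the reversal
  anchor of half-open windows: a TSS-symmetric signal profiles identically
  from either strand. Note the corollary: flipping only the strand *tag* of
  a fixed interval shifts the reversed profile by one base — that is a
  property of half-open windows, not a bug.

## What the synthetic generator emulates — and what it does not

`make_collection()` fabricates a complete testbed: a toy genome (default 1
chromosome × 1 Mb), evenly spaced genes with alternating strands written as
a valid GTF, and bigWig tracks whose per-base signal is
`baseline + |N(0, noise_sd)|` — half-normal noise keeps coverage
non-negative, like real depth signal. Enriched tracks add a *triangular*
peak (height `peak_amplitude`, half-width `w`) at each enriched gene's TSS.
The triangle is chosen over a Gaussian because its per-base sum is exactly
`amplitude × w`, giving closed-form expected means for oracle tests. The
defaults (100 genes, 20 tracks, amplitude 3× noise SD at 24 genes) mirror a
small promoter query against a modest catalogue and keep a full
generate-analyze round trip around half a minute.

The generator does **not** emulate: read-level artifacts (no FASTQ/BAM),
autocorrelated coverage from fragment-length smoothing, mappability holes,
copy-number waves, or peak-caller boundary effects. A green
planted-recovery test therefore establishes that the statistics and
plumbing are correct, not that the method's power on real chromatin data
matches any published figure.

One throughput knob matters for simulation studies: `noise_bin` draws noise
once per bin of that many bases (default 1 = per-base). Writing millions of
distinct per-base values into bigWig is the single slowest step on one CPU,
so the large acceptance simulations use `noise_bin = 10`; the t-test
operates across intervals, not bases, so this changes runtime, not the
statistics under test. Planted peaks are always per-base.

## What the acceptance suite does and does not establish

The acceptance tests are property-based, scaled to a single-CPU budget with
rates and bands kept as stated: (1) the coverage primitive agrees with an
independent per-base expansion oracle to 1e-9 relative over 1000 random
intervals; (2) the Welch implementation agrees with direct formula
evaluation and `stats::t.test` to 1e-12, and $t$/$p$/ranking are invariant
to the log base to 1e-10; (3) Bonferroni reproduces the canonical capping
pattern (a raw 0.0093 corrects to 1.0; 6.7e-6 × 358 ≈ 0.0024); (4) on 400
simulated null tracks the raw $p$ fraction below 0.05 falls in
[0.025, 0.075] and passes a Kolmogorov–Smirnov uniformity check at the 0.01
level; (5) a planted track (amplitude 3× noise SD at 24 query promoters vs
1000 background promoters) ranks first with Bonferroni $p < 0.05$ in ≥ 95 %
of seeded replicates (20 replicates in the shipped suite); (6) minus-strand
profiles equal an explicit per-base reversal oracle exactly; (7) identical
configuration and seed reproduce byte-identical report and truth files.
Headline numbers from hosted many-hundred-track collections are *not*
reproduced here — they depend on data that no desk-scale fixture can stand
in for.

## Known limitations

* No bigBed, BAM-to-coverage, or remote (URL) track access; peaks enter as
  text BED/narrowPeak.
* Bonferroni is the only multiplicity correction, matching the report
  format; FDR alternatives would be a straightforward extension but are out
  of scope.
* No assembly liftover; annotation and track collection must share a build,
  and the pairing is the user's assertion.
* The hypergeometric peak-overlap route is deliberately absent — the whole
  point of the coverage-based design is to avoid pre-computed peak sets.
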