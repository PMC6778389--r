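---
title: "Methods: clustering and enhancer prediction from 5'-end data"
author: "capclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering and enhancer prediction from 5'-end data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capclust)
```

## The data model

5'-end assays (CAGE, PRO-Cap and relatives) sequence only the 5' end of
capped RNAs. After mapping, the data reduce to **CTSSs**: for every basepair
and strand, the number of tag 5' ends starting there, per library. Most
basepairs carry no signal, so capclust stores tracks sparsely — one row per
nonzero basepair — and all coordinates are 0-based half-open (the BigWig/BED
convention, which both the input and output formats use; a CTSS is a width-1
interval). Minus-strand tracks encoded with negative values are accepted via
`negative_minus = TRUE`.

Counts are normalized to tags-per-million (TPM), `count * 1e6 /
library_size`, with the library size fixed at assembly time on the raw
tracks: filtering CTSSs afterwards changes which positions are trusted, not
how deeply a library was sequenced. The per-strand, per-basepair sum of TPM
over samples is the **pooled signal**; without filtering its total is
`n_samples * 1e6`, a conservation law the tests assert. An optional support
filter (`support_filter_ctss()`) removes basepairs seen in too few samples
before pooling, which makes the pooled signal robust when many or noisy
libraries are combined.

## Unidirectional tag clusters (slice-reduce)

RNA polymerase rarely initiates from a single basepair; nearby CTSSs on one
strand form a **tag cluster** (TC), the operational TSS candidate. Calling is
slice-reduce: drop basepairs with pooled signal below a threshold (slice),
then merge surviving same-strand basepairs whose gap — the number of
sliced-away basepairs strictly between them — is at most the merge distance
(reduce). The cluster peak is the basepair with maximal pooled signal, ties
going to the smallest coordinate so results are deterministic; the cluster
score sums pooled signal over *surviving* basepairs only, which is the literal
slice-then-reduce semantics (sub-threshold basepairs inside the span
contribute nothing).

Defaults are a slice threshold of 0.1 pooled TPM and a merge distance of
20 bp. Both are deliberately small relative to the downstream expression
filter ("more than 1 TPM in at least two samples", the `tc_pipeline()`
default) and to typical TC widths, and both are exposed. Raising the
threshold can only remove clustered signal and raising the merge distance can
only reduce the cluster count; the tests check these monotonicities and an
exact equivalence with a brute-force run enumerator on random tracks.

## Bidirectional clusters and the balance score

Active enhancers transcribe unstable eRNAs divergently: minus-strand signal
just upstream, plus-strand signal just downstream. For a candidate midpoint
`m` and window `w` (default 200 bp), four arm sums are taken from the pooled
track: PU (plus over `[m-w, m)`), PD (plus over `[m, m+w]`), MD (minus over
`[m-w, m]`), MU (minus over `(m, m+w]`). The inclusivity is chosen so every
basepair of signal lands in exactly one arm per strand; it is configurable in
effect through the window size only, since the contract is the partition.
With arm fractions `f` and the ideal divergent distribution
`q = (0, 1/2, 0, 1/2)`, the **balance score** is the Bhattacharyya
coefficient

\[ B = \sum_i \sqrt{f_i q_i} = \sqrt{f_{PD}/2} + \sqrt{f_{MD}/2}. \]

`B = 1` exactly when PD and MD each hold half the signal and nothing sits on
the upstream arms; with all signal on a single strand `B` cannot exceed
`sqrt(1/2) ≈ 0.707`. `B` is invariant to scaling all four sums. Basepairs
with an empty PD or MD arm are skipped outright — their score is below any
cutoff above 0.707, so with the default cutoff of 0.95 the skip is purely an
optimization; `cluster_bidirectional()` refuses cutoffs at or below
`sqrt(1/2)` for exactly this reason. Window monotonicity is *not* assumed
anywhere: changing `w` can move scores in either direction.

Calling is again slice-reduce, now on the balance track: basepairs at or
above the cutoff are kept, runs with gaps up to `w` merged (passing positions
from one locus are separated by at most the window scale), and each run is
expanded by `w` on both sides, clipped to the chromosome. The expansion
guarantees the reported span contains both arms' signal, so quantifying the
span across both strands captures the locus' full output. The midpoint is the
basepair of maximal balance (ties leftmost). `bc_pipeline()` quantifies raw
counts and filters on tag support with `>=` semantics (thresholds phrased in
tags, e.g. "at least 1 tag in more than 6 samples", use inclusive
comparison; thresholds phrased in TPM default to strict).

## Hierarchical annotation and gene-level analysis

Clusters are annotated against transcript models by testing the anchor
basepair — the TC peak or BC midpoint, the best single-bp estimate of the
initiation site — against every transcript and keeping the highest-priority
category: promoter, proximal, 5'UTR, 3'UTR, CDS, exon, intron, antisense,
intergenic. The hierarchy resolves isoform ambiguity (one transcript's
annotated promoter is another's 5'UTR) in favour of the most likely biology.
Defaults: promoter = within 100 bp of an annotated TSS, proximal = up to
1 kbp upstream; both configurable, as is the category order. Stranded
clusters match same-strand transcripts except for antisense (opposite strand
only); unstranded BCs match either strand and can never be antisense.

Enhancer candidates are BCs annotated intron or intergenic, with one
span-level addition: any BC whose *span* overlaps exonic sequence is dropped,
because exon contamination (e.g. highly expressed bidirectional promoters or
recapping artefacts) is a property of the whole cluster, not its midpoint.

TCs are assigned to genes when the peak falls in the gene's span (union of
its transcripts) extended 1 kbp upstream, same strand; overlaps between
genes resolve to the gene with the nearest annotated TSS and exact ties stay
unassigned rather than guessing. Summing assigned TCs per gene yields a
count matrix for standard differential-expression tooling; the sum of the
gene matrix equals the sum over assigned TCs by construction (tested). The
composition filter for alternative-TSS analysis keeps a gene-assigned TC
when its share of the gene's expression strictly exceeds `min_fraction`
(default 10%) in strictly more than `min_samples` samples; samples where the
gene total is zero count as failing, and unassigned TCs are never touched.
The strict inequalities follow the usual phrasing of these thresholds
("more than 10% ... in more than 6 samples"), whereas `feature_support()`
uses "at least `min_samples`" — the two rules are documented separately on
purpose.

## Shape statistics

Promoter shape is summarized on the pooled signal within each TC. The
interquantile width walks the cluster left to right and takes the first
basepair where the cumulative fraction reaches `lower` (default 0.05) and the
first where it reaches `upper` (default 0.95); the width is the distance
between them plus one. First-crossing, no interpolation: at basepair
resolution this is deterministic and robust to straggler CTSSs at the edges.
Widths at most 10 bp are classified sharp (the boundary value counts as
sharp; the conventional threshold does not specify inclusivity, so ours is
documented), larger ones broad. Shannon entropy of the within-cluster signal
fractions is reported in bits alongside, and `shape_stat()` accepts any
user statistic `f(pos, score)` through the same interface. Tightening the
quantiles can never widen the interval, and both statistics are invariant to
uniform scaling of the signal; both properties are tested.

## Co-expression links and enhancer stretches

TC-enhancer links are predicted from co-expression: all pairs within 10 kbp
(measured TC peak to enhancer midpoint by default; an edge-to-edge option
exists) are correlated across samples with Kendall's tau-b — count matrices
are tie-rich, and tau-b handles ties — with two-sided p-values, then
Benjamini-Hochberg adjusted across **all** computed pairs. Positivity
(`estimate > 0`) is applied as a filter on the estimate, separate from the
FDR, since the two are reported separately. Pairs with a constant profile
have no defined correlation and are dropped with a warning rather than
imputed. Because a transcribed enhancer's own arms are themselves TCs,
`remove_enhancer_arms()` makes the TC set disjoint from the enhancer set
before pairing; otherwise every enhancer would trivially "link" to itself.

Stretches ("super enhancers") chain enhancers whose edge-to-edge gap is
strictly below 12.5 kbp (single linkage); chains with at least 4 members are
reported — the smallest stretch size we consider informative — with the mean
pairwise correlation over member expression profiles as a concordance
summary (undefined for a single quantified member).

## The synthetic data generator

`simulate_dataset()` emulates the signal structure the pipeline is built
for, with ground truth, so every stage is testable without downloads:

* **Sharp TCs** place tags at offsets −2..+2 around the peak (60% at the
  peak), so at least 90% of tags fall within 2 bp.
* **Broad TCs** mix a dominant summit (30% of tags) with a Gaussian spread
  over a 40–100 bp region — the dominant-CTSS-in-a-broad-region shape
  typical of ubiquitously expressed promoters. Their interquantile widths
  land well above 10 bp while sharp TCs stay below.
* **Enhancers** emit divergent tags: minus-strand at 10–180 bp upstream,
  plus-strand downstream, totals split binomially around 50/50, so the
  balance at the true midpoint approaches 1 at high expression.
* **Counts** per feature and sample are negative-binomial (overdispersion
  0.2) around a mean of 50 tags, modulated by a per-feature log-normal
  activity (log-SD 1) across samples — biological replicates are
  overdispersed, and correlation tests need realistic variance. Designated
  TC-enhancer pairs share a latent activity with correlation 0.8.
* **Noise** is a sparse field of independent single-tag CTSSs at 1e-5 per
  bp per strand per sample.
* **Transcript models** wrap each planted TC (TSS at the peak, two exons, a
  CDS), so annotation, gene assignment and the composition filter can be
  exercised against known answers.

Defaults are 5 samples, 50 TCs (half sharp), 20 enhancers on a 2 Mbp
chromosome with features in jittered 4 kbp slots; the link-power analysis
uses 50 samples and 20 linked pairs. These sizes keep the full suite around
a minute while leaving no planted structure untested. What the generator
does **not** emulate: mapping artefacts, promoter sequence content, batch
effects, chromosome-scale covariates, or distance-dependent correlation
decay. Passing recovery tests therefore demonstrates algorithmic
correctness on data with the assumed structure, not performance on any
particular real library.

Recovery is scored by interval overlap plus an anchor tolerance of 5 bp for
TC peaks and 50 bp for enhancer midpoints — stricter than the default merge
distances, so a match cannot be an artifact of generous clustering.

## Numerical and degenerate-input choices

* Peak and midpoint ties break to the smallest coordinate; outputs are
  sorted, so reruns are byte-identical.
* Zero-signal clusters are an error in shape statistics, not an NA: they
  indicate the clusters and pooled track are out of sync.
* An empty track is a valid input everywhere and yields empty outputs; a
  BigWig cannot represent an empty track, so `write_track()` refuses and
  suggests bedGraph (which round-trips as a header-only file).
* BigWig values within 1e-6 of an integer are rounded on import; anything
  further off is a format error, as are negative counts (unless
  `negative_minus` explains them).
* Chromosomes present in the genome but absent from a track contribute zero
  signal; chromosomes in a track but absent from the genome warn and are
  dropped (extra contigs are common and harmless).
* Fractional (pooled) values are written to bedGraph with six decimals;
  integer counts round-trip bit-exactly.

## Limitations

Balance scoring uses a single fixed window; loci whose arms sit further than
`w` from the midpoint score low, and no multi-scale search is attempted.
Link prediction is correlation-based hypothesis generation, not evidence of
physical contact, and the FDR is controlled per analysis, not per genome.
Power-law normalization, TSS-shift statistics and differential expression
are out of scope: the expression matrices are designed to hand off to the
dedicated tools for those tasks.
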