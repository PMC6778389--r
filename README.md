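# capclust

Tag clustering and enhancer prediction from 5'-end transcriptome data.

5'-end assays — CAGE, PRO-Cap and related protocols — sequence only the 5'
ends of capped RNAs, piling reads up at transcription start sites with
basepair resolution. After mapping, each library reduces to **CTSSs**: per
basepair and strand, the number of tag 5' ends starting there. capclust is
an R package for everything downstream of that point, for researchers who
want TSS and enhancer candidates plus count matrices ready for standard
differential-expression tooling:

* **Import**: sparse per-bp stranded tracks from BigWig or bedGraph, a
  sample sheet, and a chrom-sizes file; everything is 0-based half-open.
* **Normalize and pool**: tags-per-million per library, summed across
  libraries into a pooled signal, optionally after a sample-support filter.
* **Tag clusters (TSS candidates)** by slice-reduce: discard basepairs with
  pooled signal below a threshold, merge surviving same-strand basepairs
  within a merge distance; report span, peak and score.
* **Bidirectional clusters (enhancer candidates)**: at each candidate
  midpoint, windowed arm sums (PU, PD, MU, MD; 200 bp default) are compared
  to the ideal divergent distribution (50% PD, 50% MD) with the
  Bhattacharyya coefficient,

  `balance = sqrt(0.5 * fPD) + sqrt(0.5 * fMD)`,

  which is 1 for perfectly balanced divergent transcription and at most
  sqrt(0.5) for single-strand signal; basepairs above a 0.95 cutoff are
  merged into clusters.
* **Hierarchical annotation** against GTF transcript models (promoter,
  proximal, 5'UTR, 3'UTR, CDS, exon, intron, antisense, intergenic) and
  enhancer-candidate selection (intronic/intergenic, exon-free spans).
* **Shape statistics**: 5–95% interquantile width and Shannon entropy per
  TC, with the conventional sharp (width <= 10 bp) vs broad classification.
* **Gene-level analysis**: assignment of TCs to genes, gene count matrices,
  and the composition filter for alternative TSS candidates (drop TCs below
  10% of gene expression).
* **Links and stretches**: TC-enhancer co-expression within 10 kbp
  (Kendall's tau-b, BH-adjusted), and enhancer stretches chained at
  gaps under 12.5 kbp with average pairwise member correlation.
* **Synthetic data**: a seeded generator planting sharp/broad TCs, divergent
  enhancer loci, transcript models, co-expressed TC-enhancer pairs and
  noise, with ground truth and precision/recall scoring.

All user-facing functions take and return tidy data frames, so analyses
compose with the pipe; `tidy()`/`glance()` methods and `plot_*()` helpers
(ggplot2) cover the common summaries.

## Worked example

```r
library(capclust)

sim <- simulate_dataset(sim_config(seed = 42))   # 5 samples, 50 TCs, 20 enhancers
tc  <- tc_pipeline(sim$dataset)                  # pool, slice-reduce, filter >1 TPM in >=2 samples
bc  <- bc_pipeline(sim$dataset, min_count = 1, min_samples = 2)
tc
#> Tag clusters: 92 clusters x 5 samples
bc
#> Bidirectional clusters: 22 clusters x 5 samples

tidy(tc)
#> # A tibble: 92 x 8
#>    feature_id         chrom start   end strand  peak peak_value  score
#>  1 chrS:3363-3532;-   chrS   3363  3532 -       3391      1359. 42235.
#>  2 chrS:3553-3710;+   chrS   3553  3710 +       3635      1026. 35656.
#>  ...
```

Each cluster row is a genomic interval with its peak (the basepair of
maximal pooled signal) and score (summed pooled TPM). The 92 called TCs are
the 50 planted promoters plus the two eRNA arms of each transcribed
enhancer — which is why linking first makes the sets disjoint:

```r
tss <- remove_enhancer_arms(tc$clusters, bc$clusters)
cluster_shape(tss, tc$pooled) |> dplyr::count(shape_class)
#>   broad sharp
#>      25    24          # the planted 25/25 mix, one TC lost to an overlap

evaluate_recovery(bc$clusters, sim$truth, "enhancer")
#> # A tibble: 1 x 7
#>   type     n_true n_called n_matched precision recall peak_distances
#> 1 enhancer     20       22        20     0.909      1 <dbl [20]>
```

Every planted enhancer is recovered (recall 1) with 2 spurious calls from
background noise (precision 0.91). With more samples and planted
co-expressed pairs, links come out of the same objects:

```r
sim <- simulate_dataset(sim_config(seed = 42, n_samples = 50, n_links = 10))
tc  <- tc_pipeline(sim$dataset)
bc  <- bc_pipeline(sim$dataset, min_count = 1, min_samples = 2)
tss <- remove_enhancer_arms(tc$clusters, bc$clusters)
pairs <- candidate_pairs(tss, bc$clusters, max_dist = 10000)
links <- correlate_links(pairs, tc$expr[tc$expr$feature_id %in% tss$feature_id, ],
                         bc$expr, method = "kendall")
#> 193 pairs; 88 positively correlated; 12 significant at FDR < 0.05
dplyr::arrange(links, p_adj) |> head(3)
#>   tc_id              enhancer_id        chrom distance estimate  p_value   p_adj
#> 1 chrS:60147-60152;- chrS:64108-64590;. chrS      4189    0.588  2.69e-9 5.19e-7
#> 2 chrS:36267-36272;+ chrS:40014-40498;. chrS      3978    0.526  9.22e-8 8.89e-6
#> 3 chrS:19871-19876;- chrS:23548-24032;. chrS      3904    0.493  5.74e-7 3.70e-5
```

The strongest links are the planted co-expressed TC-enhancer pairs (all at
~4 kbp, the planted spacing), with tau around 0.5-0.6 — what a latent
activity correlation of 0.8 looks like after negative-binomial counting
noise.

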