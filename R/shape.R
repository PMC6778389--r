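# Pooled signal of each cluster as a list of (pos, score) tibbles,
# same-strand, positions within [start, end).
.cluster_signal <- function(clusters, pooled) {
  clusters <- as_tibble(clusters)
  pgr <- GenomicRanges::GRanges(
    pooled$chrom, IRanges::IRanges(pooled$pos + 1, width = 1),
    strand = pooled$strand
  )
  cstrand <- ifelse(clusters$strand %in% c("+", "-"), clusters$strand, "*")
  cgr <- GenomicRanges::GRanges(
    clusters$chrom, IRanges::IRanges(clusters$start + 1, clusters$end),
    strand = cstrand
  )
  hits <- GenomicRanges::findOverlaps(pgr, cgr)
  sig <- split(
    tibble(pos = pooled$pos[S4Vectors::queryHits(hits)],
           score = pooled$score[S4Vectors::queryHits(hits)]),
    factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(clusters)))
  )
  lapply(sig, function(s) dplyr::arrange(s, .data$pos))
}

#' Interquantile width of tag clusters
#'
#' The genomic width covering the central `lower`-to-`upper` cumulative
#' fraction of a cluster's pooled signal: walking the cluster's basepairs
#' left to right, `lowpos` is the first basepair where the cumulative
#' fraction reaches `lower` and `highpos` the first where it reaches `upper`;
#' the width is `highpos - lowpos + 1`. Unlike the full cluster width this is
#' robust to a few straggler CTSSs at the edges. Quantile positions are
#' first-crossings of the cumulative sum (no interpolation), which is
#' deterministic at bp resolution.
#'
#' @param clusters Cluster tibble (see [cluster_unidirectional()]).
#' @param pooled A pooled track.
#' @param lower,upper Cumulative-fraction bounds (defaults 0.05 and 0.95).
#' @return Numeric vector of widths in bp, one per cluster.
#' @export
cluster_iqr <- function(clusters, pooled, lower = 0.05, upper = 0.95) {
  .assert(lower >= 0 && lower < upper && upper <= 1,
          "quantiles must satisfy 0 <= lower < upper <= 1")
  sig <- .cluster_signal(clusters, pooled)
  vapply(sig, function(s) {
    .assert(nrow(s) > 0 && sum(s$score) > 0, "zero-signal cluster")
    cum <- cumsum(s$score) / sum(s$score)
    lowpos <- s$pos[which(cum >= lower)[1]]
    highpos <- s$pos[which(cum >= upper)[1]]
    highpos - lowpos + 1
  }, numeric(1), USE.NAMES = FALSE)
}

#' Shannon entropy of tag clusters
#'
#' Entropy (bits) of the per-basepair signal fractions within each cluster:
#' `-sum(p * log2(p))`. 0 for a single-bp cluster; `log2(n)` for signal
#' uniform over `n` basepairs.
#'
#' @inheritParams cluster_iqr
#' @return Numeric vector of entropies in bits.
#' @export
cluster_entropy <- function(clusters, pooled) {
  sig <- .cluster_signal(clusters, pooled)
  vapply(sig, function(s) {
    .assert(nrow(s) > 0 && sum(s$score) > 0, "zero-signal cluster")
    p <- s$score / sum(s$score)
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify clusters as sharp or broad
#'
#' Sharp promoters have their signal concentrated in a narrow region; the
#' conventional rule classifies a cluster as sharp when its interquantile
#' width is at most `sharp_max` bp (boundary width counts as sharp).
#'
#' @param widths Interquantile widths from [cluster_iqr()].
#' @param sharp_max Largest width still called sharp (default 10 bp).
#' @return Character vector, `"sharp"` or `"broad"`.
#' @export
classify_shape <- function(widths, sharp_max = 10) {
  ifelse(widths <= sharp_max, "sharp", "broad")
}

#' Apply a custom shape statistic to each cluster
#'
#' Any function mapping a cluster's signal to a number can be used as a shape
#' statistic through the same interface as [cluster_iqr()].
#'
#' @inheritParams cluster_iqr
#' @param fun Function of two vectors, `pos` (basepair positions, ascending)
#'   and `score` (pooled signal), returning a single number.
#' @return Numeric vector, one value per cluster.
#' @export
shape_stat <- function(clusters, pooled, fun) {
  sig <- .cluster_signal(clusters, pooled)
  vapply(sig, function(s) fun(s$pos, s$score), numeric(1), USE.NAMES = FALSE)
}

#' Shape summary of tag clusters
#'
#' Convenience wrapper computing interquantile width, entropy and the
#' sharp/broad class for every cluster.
#'
#' @inheritParams cluster_iqr
#' @param sharp_max Passed to [classify_shape()].
#' @return `clusters` with `iqr`, `entropy` and `shape_class` columns added.
#' @export
cluster_shape <- function(clusters, pooled, lower = 0.05, upper = 0.95,
                          sharp_max = 10) {
  clusters <- as_tibble(clusters)
  clusters$iqr <- cluster_iqr(clusters, pooled, lower, upper)
  clusters$entropy <- cluster_entropy(clusters, pooled)
  clusters$shape_class <- classify_shape(clusters$iqr, sharp_max)
  clusters
}
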