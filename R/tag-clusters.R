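#' Call unidirectional tag clusters by slice-reduce
#'
#' Tag clusters (TCs) group nearby CTSSs on the same strand into TSS
#' candidates. Basepairs with pooled signal below `threshold` are discarded
#' (slice); surviving basepairs on the same strand separated by at most
#' `merge_dist` sliced-away basepairs are merged into one cluster (reduce).
#' The cluster spans the first through last survivor; its peak is the
#' basepair with the highest pooled signal (ties: leftmost) and its score is
#' the summed pooled signal over the surviving basepairs only.
#'
#' @param pooled A pooled track (see [pool_ctss()]).
#' @param threshold Slice threshold in pooled TPM; basepairs with
#'   `score < threshold` are dropped.
#' @param merge_dist Maximum number of basepairs strictly between consecutive
#'   survivors that still get merged.
#' @return Tibble of clusters: `feature_id` (`chrom:start-end;strand`),
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `peak`,
#'   `peak_value`, `score`.
#' @export
cluster_unidirectional <- function(pooled, threshold = 0.1, merge_dist = 20) {
  .assert(threshold >= 0 && merge_dist >= 0,
          "threshold and merge_dist must be >= 0")
  surv <- pooled %>%
    dplyr::filter(.data$score >= .env$threshold) %>%
    dplyr::arrange(.data$chrom, .data$strand, .data$pos)
  if (nrow(surv) == 0) {
    return(tibble(feature_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  peak = numeric(), peak_value = numeric(), score = numeric()))
  }
  gap <- surv$pos - dplyr::lag(surv$pos) - 1
  new_grp <- surv$chrom != dplyr::lag(surv$chrom) |
    surv$strand != dplyr::lag(surv$strand) |
    gap > merge_dist
  new_grp[1] <- TRUE
  surv$cluster <- cumsum(new_grp)
  out <- surv %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos),
      end = max(.data$pos) + 1,
      strand = .data$strand[1],
      peak = .data$pos[which.max(.data$score)],
      peak_value = max(.data$score),
      score = sum(.data$score),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$start, .data$strand) %>%
    dplyr::select(-"cluster")
  out$feature_id <- sprintf("%s:%d-%d;%s", out$chrom, as.integer(out$start),
                            as.integer(out$end), out$strand)
  out[, c("feature_id", "chrom", "start", "end", "strand", "peak",
          "peak_value", "score")]
}

#' Tag-cluster pipeline: pool, slice-reduce, quantify, support-filter
#'
#' Runs the full TC workflow: TPM normalization (if needed), pooling, slice-
#' reduce clustering, same-strand quantification and removal of clusters that
#' fail the expression-support rule (by default "> 1 TPM in at least two
#' samples").
#'
#' @param dataset A [ctss_dataset()].
#' @param threshold,merge_dist Passed to [cluster_unidirectional()].
#' @param min_tpm,min_samples Support rule: keep clusters with TPM above
#'   `min_tpm` in at least `min_samples` samples.
#' @param strict Use `>` (default) or `>=` on the TPM threshold.
#' @return List of class `tc_result` with elements `clusters` (tibble) and
#'   `expr` (`ctss_expr` count table), plus the pooled track used.
#' @export
tc_pipeline <- function(dataset, threshold = 0.1, merge_dist = 20,
                        min_tpm = 1, min_samples = 2, strict = TRUE) {
  if (!"tpm" %in% names(dataset$ctss)) dataset <- normalize_tpm(dataset)
  pooled <- pool_ctss(dataset)
  clusters <- cluster_unidirectional(pooled, threshold, merge_dist)
  expr <- quantify_ranges(dataset, clusters, "same-strand")
  keep <- feature_support(expr, min_tpm, min_samples, use_tpm = TRUE,
                          strict = strict)
  structure(
    list(clusters = clusters[keep, , drop = FALSE],
         expr = expr[keep, , drop = FALSE],
         pooled = pooled),
    class = "tc_result"
  )
}

#' @export
print.tc_result <- function(x, ...) {
  cat("Tag clusters:", nrow(x$clusters), "clusters x",
      length(expr_samples(x$expr)), "samples\n")
  invisible(x)
}

#' @rdname tc_pipeline
#' @param x A `tc_result`.
#' @param ... Unused.
#' @export
tidy.tc_result <- function(x, ...) as_tibble(x$clusters)

#' @rdname tc_pipeline
#' @export
glance.tc_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_samples = length(expr_samples(x$expr)),
         total_score = sum(x$clusters$score))
}
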