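#' Candidate TC-enhancer pairs within a distance window
#'
#' Enumerates all (tag cluster, enhancer candidate) pairs on the same
#' chromosome whose anchors lie within `max_dist` of each other. By default
#' distance is measured from the TC peak to the enhancer max-balance
#' midpoint; `use = "edge"` measures edge-to-edge between the spans instead.
#'
#' @param tcs Tag-cluster tibble (needs `feature_id`, `chrom`, `peak`).
#' @param enhancers Enhancer tibble (needs `feature_id`, `chrom`,
#'   `midpoint`).
#' @param max_dist Maximum distance in bp (default 10000).
#' @param use `"anchor"` (peak to midpoint) or `"edge"` (span to span).
#' @return Tibble `tc_id`, `enhancer_id`, `chrom`, `distance` (signed,
#'   enhancer anchor minus TC anchor; for `use = "edge"` the signed gap, 0
#'   when spans overlap).
#' @export
candidate_pairs <- function(tcs, enhancers, max_dist = 10000,
                            use = c("anchor", "edge")) {
  use <- match.arg(use)
  .assert(max_dist > 0, "max_dist must be positive")
  tc <- tibble(tc_id = tcs$feature_id, chrom = tcs$chrom,
               a = tcs$peak, s = tcs$start, e = tcs$end)
  en <- tibble(enhancer_id = enhancers$feature_id, chrom = enhancers$chrom,
               a = enhancers$midpoint, s = enhancers$start, e = enhancers$end)
  pairs <- dplyr::inner_join(tc, en, by = "chrom", suffix = c(".tc", ".en"),
                             relationship = "many-to-many")
  if (use == "anchor") {
    pairs$distance <- pairs$a.en - pairs$a.tc
  } else {
    gap_right <- pairs$s.en - pairs$e.tc  # enhancer right of TC
    gap_left <- pairs$s.tc - pairs$e.en
    pairs$distance <- dplyr::case_when(
      gap_right > 0 ~ gap_right,
      gap_left > 0 ~ -gap_left,
      TRUE ~ 0
    )
  }
  pairs %>%
    dplyr::filter(abs(.data$distance) <= .env$max_dist) %>%
    dplyr::select("tc_id", "enhancer_id", "chrom", "distance")
}

.cor_methods <- c("kendall", "pearson", "spearman")

.pair_cor <- function(x, y, method) {
  if (is.function(method)) {
    res <- method(x, y)
    return(c(estimate = unname(res$estimate), p = unname(res$p.value)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  c(estimate = unname(ct$estimate), p = unname(ct$p.value))
}

#' Correlate candidate pairs and control FDR
#'
#' Computes, for every candidate pair, the co-expression correlation between
#' the TC and enhancer count profiles across samples (Kendall's tau-b by
#' default; ties are common in count matrices and tau-b handles them) with a
#' two-sided p-value, then adjusts p-values across all computed pairs with
#' Benjamini-Hochberg. Pairs where either profile is constant have no defined
#' correlation and are dropped with a warning. Positively correlated links
#' are those with `estimate > 0`.
#'
#' @param pairs Tibble from [candidate_pairs()].
#' @param tc_expr,enh_expr `ctss_expr` count tables sharing sample order.
#' @param method `"kendall"`, `"pearson"`, `"spearman"`, or a function
#'   `f(x, y)` returning a list with elements `estimate` and `p.value`.
#' @return Tibble `tc_id`, `enhancer_id`, `chrom`, `distance`, `estimate`,
#'   `p_value`, `p_adj`.
#' @export
correlate_links <- function(pairs, tc_expr, enh_expr, method = "kendall") {
  if (!is.function(method)) method <- match.arg(method, .cor_methods)
  .assert(identical(expr_samples(tc_expr), expr_samples(enh_expr)),
          "tc and enhancer matrices must share sample order")
  tm <- expr_counts(tc_expr)
  em <- expr_counts(enh_expr)
  .assert(all(pairs$tc_id %in% rownames(tm)), "unknown tc_id in pairs")
  .assert(all(pairs$enhancer_id %in% rownames(em)), "unknown enhancer_id in pairs")
  xs <- tm[pairs$tc_id, , drop = FALSE]
  ys <- em[pairs$enhancer_id, , drop = FALSE]
  const <- apply(xs, 1, stats::sd) == 0 | apply(ys, 1, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " pair(s) dropped: constant expression vector",
            call. = FALSE)
  }
  pairs <- pairs[!const, , drop = FALSE]
  xs <- xs[!const, , drop = FALSE]
  ys <- ys[!const, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(dplyr::mutate(pairs, estimate = numeric(0), p_value = numeric(0),
                         p_adj = numeric(0)))
  }
  res <- vapply(seq_len(nrow(pairs)), function(i) {
    .pair_cor(xs[i, ], ys[i, ], method)
  }, numeric(2))
  pairs$estimate <- unname(res["estimate", ])
  pairs$p_value <- unname(res["p", ])
  pairs$p_adj <- bh_adjust(pairs$p_value)
  pairs
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1) with input
#' validation; a thin wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Find enhancer stretches ("super enhancers")
#'
#' Chains enhancer candidates by single linkage: consecutive enhancers on a
#' chromosome whose edge-to-edge gap is strictly less than `merge_dist` join
#' the same chain; chains with at least `min_members` members are reported
#' as stretches spanning the first start through the last end.
#'
#' @param enhancers Enhancer tibble (needs `feature_id`, `chrom`, `start`,
#'   `end`), any order.
#' @param merge_dist Gap threshold in bp (default 12500).
#' @param min_members Minimum number of enhancers per stretch (default 4).
#' @return Tibble `stretch_id`, `chrom`, `start`, `end`, `n_members`,
#'   `members` (list column of enhancer ids).
#' @export
find_stretches <- function(enhancers, merge_dist = 12500, min_members = 4) {
  enh <- dplyr::arrange(as_tibble(enhancers), .data$chrom, .data$start)
  if (nrow(enh) == 0) {
    return(tibble(stretch_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), n_members = integer(),
                  members = list()))
  }
  gap <- enh$start - dplyr::lag(cummax_by_chrom(enh))
  new_grp <- enh$chrom != dplyr::lag(enh$chrom) | gap >= merge_dist
  new_grp[1] <- TRUE
  enh$chain <- cumsum(new_grp)
  out <- enh %>%
    dplyr::group_by(.data$chain) %>%
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start), end = max(.data$end),
      n_members = dplyr::n(),
      members = list(.data$feature_id),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_members >= .env$min_members) %>%
    dplyr::select(-"chain")
  out$stretch_id <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                            as.integer(out$end))
  out[, c("stretch_id", "chrom", "start", "end", "n_members", "members")]
}

# Running maximum of `end` within each chromosome (spans may be nested).
cummax_by_chrom <- function(enh) {
  stats::ave(enh$end, enh$chrom, FUN = cummax)
}

#' Average pairwise correlation within enhancer stretches
#'
#' For each stretch, the mean correlation over all unordered pairs of member
#' enhancers' expression profiles — concordant changes across samples suggest
#' the stretch acts jointly. Stretches with a single quantified member have
#' no pairs and get `NA`.
#'
#' @param stretches Tibble from [find_stretches()].
#' @param enh_expr `ctss_expr` count table of the enhancers.
#' @param method Correlation method for [stats::cor()] (default
#'   `"kendall"`).
#' @return `stretches` with an `avg_cor` column.
#' @export
stretch_correlations <- function(stretches, enh_expr, method = "kendall") {
  m <- expr_counts(enh_expr)
  stretches$avg_cor <- vapply(stretches$members, function(ids) {
    ids <- intersect(ids, rownames(m))
    if (length(ids) < 2) return(NA_real_)
    cm <- suppressWarnings(stats::cor(t(m[ids, , drop = FALSE]),
                                      method = method))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  stretches
}

#' Remove tag clusters that overlap enhancer candidates
#'
#' The two arms of a transcribed enhancer are themselves unidirectional
#' clusters, so the TC set called on the same data contains every enhancer's
#' own eRNA arms. Before co-expression linking the TC set is made disjoint
#' from the enhancer set: correlating an enhancer with its own arms would
#' produce trivial self-links.
#'
#' @param tcs Tag-cluster tibble.
#' @param enhancers Enhancer/bidirectional-cluster tibble.
#' @return `tcs` without rows whose span overlaps an enhancer span.
#' @export
remove_enhancer_arms <- function(tcs, enhancers) {
  if (nrow(tcs) == 0 || nrow(enhancers) == 0) return(tcs)
  tgr <- .gr0(tcs$chrom, tcs$start, tcs$end, "*")
  egr <- .gr0(enhancers$chrom, enhancers$start, enhancers$end, "*")
  hit <- IRanges::overlapsAny(tgr, egr, ignore.strand = TRUE)
  tcs[!hit, , drop = FALSE]
}
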