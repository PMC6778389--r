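#' Balance score of four windowed arm sums
#'
#' Quantifies how close windowed signal around a candidate midpoint is to
#' perfect divergent (bidirectional) transcription. With arm fractions
#' `f = (PU, PD, MU, MD) / total` and the ideal divergent distribution
#' `q = (0, 0.5, 0, 0.5)` (all signal split equally between the plus-strand
#' downstream arm and the minus-strand downstream arm), the score is the
#' Bhattacharyya coefficient `sum(sqrt(f * q)) = sqrt(0.5 fPD) + sqrt(0.5
#' fMD)`. It equals 1 iff `fPD = fMD = 0.5`, is at most `sqrt(0.5)` when one
#' strand carries no signal, and is invariant to scaling all four sums.
#'
#' @param pu,pd,mu,md Non-negative arm sums: plus-upstream, plus-downstream,
#'   minus-upstream, minus-downstream (downstream is strand-relative: PD is
#'   plus signal right of the midpoint, MD minus signal left of it).
#'   Vectorized.
#' @return Balance in `[0, 1]`; `NA` where the total is 0 (no signal, caller
#'   must skip such basepairs).
#' @export
balance_score <- function(pu, pd, mu, md) {
  total <- pu + pd + mu + md
  .assert(all(c(pu, pd, mu, md) >= 0), "arm sums must be non-negative")
  out <- sqrt(0.5 * pd / total) + sqrt(0.5 * md / total)
  out[total == 0] <- NA_real_
  out
}

# Windowed sum helper over a cumulative vector: sum of v[i..j] (1-based,
# clipped to [1, n]); cum = c(0, cumsum(v)).
.wsum <- function(cum, i, j) {
  n <- length(cum) - 1
  cum[pmin(pmax(j, 0), n) + 1] - cum[pmin(pmax(i - 1, 0), n) + 1]
}

.balance_chrom <- function(plus, minus, window, chrom_len, skip_single_arm) {
  all_pos <- c(plus$pos, minus$pos)
  if (length(all_pos) == 0) return(NULL)
  if (skip_single_arm && (nrow(plus) == 0 || nrow(minus) == 0)) return(NULL)
  regions <- IRanges::reduce(IRanges::IRanges(all_pos - window, all_pos + window))
  purrr::map_dfr(seq_along(regions), function(k) {
    ra <- BiocGenerics::start(regions)[k]
    rb <- BiocGenerics::end(regions)[k]
    o <- max(0, ra - window)
    e <- rb + window
    if (!is.na(chrom_len)) e <- min(chrom_len - 1, e)
    n <- e - o + 1
    vp <- numeric(n)
    vm <- numeric(n)
    ip <- plus$pos >= o & plus$pos <= e
    im <- minus$pos >= o & minus$pos <= e
    vp[plus$pos[ip] - o + 1] <- plus$score[ip]
    vm[minus$pos[im] - o + 1] <- minus$score[im]
    cp <- c(0, cumsum(vp))
    cm <- c(0, cumsum(vm))
    lo <- max(ra, 0)
    hi <- if (is.na(chrom_len)) rb else min(rb, chrom_len - 1)
    if (hi < lo) return(NULL)
    mids <- lo:hi
    k1 <- mids - o + 1
    pd <- .wsum(cp, k1, k1 + window)
    pu <- .wsum(cp, k1 - window, k1 - 1)
    md <- .wsum(cm, k1 - window, k1)
    mu <- .wsum(cm, k1 + 1, k1 + window)
    keep <- if (skip_single_arm) pd > 0 & md > 0 else pd + pu + md + mu > 0
    if (!any(keep)) return(NULL)
    tibble(pos = mids[keep],
           balance = balance_score(pu[keep], pd[keep], mu[keep], md[keep]))
  })
}

#' Per-basepair balance track
#'
#' Computes the balance score at candidate midpoints along the genome from the
#' pooled track. By default basepairs where either downstream arm (PD or MD)
#' is empty are skipped outright: their balance is at most `sqrt(0.5) ~
#' 0.707`, below any useful cutoff. Set `skip_single_arm = FALSE` to score
#' every basepair with any windowed signal.
#'
#' @param pooled A pooled track (see [pool_ctss()]).
#' @param window Arm window size in bp (default 200): PD sums plus signal over
#'   `[m, m+window]`, MD minus signal over `[m-window, m]`; PU/MU are the
#'   mirrored upstream arms excluding `m`.
#' @param skip_single_arm Skip basepairs with an empty PD or MD arm.
#' @param genome Genome tibble (for chromosome bounds); defaults to the
#'   attribute carried by `pooled`.
#' @return Tibble with columns `chrom`, `pos`, `balance`.
#' @export
balance_track <- function(pooled, window = 200, skip_single_arm = TRUE,
                          genome = attr(pooled, "genome")) {
  .assert(window > 0, "window must be positive")
  by_chrom <- split(as_tibble(pooled), pooled$chrom)
  out <- purrr::imap_dfr(by_chrom, function(tk, ch) {
    len <- if (is.null(genome)) NA_real_ else
      genome$length[match(ch, genome$chrom)]
    res <- .balance_chrom(tk[tk$strand == "+", ], tk[tk$strand == "-", ],
                          window, len, skip_single_arm)
    if (is.null(res) || nrow(res) == 0) return(NULL)
    dplyr::mutate(res, chrom = ch, .before = 1)
  })
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), pos = numeric(), balance = numeric())
  }
  out
}

#' Call bidirectional clusters (enhancer candidates)
#'
#' Slice-reduce on the balance track: basepairs with balance at or above
#' `cutoff` are kept, runs separated by at most `merge_gap` basepairs are
#' merged, and each run is expanded by `window` on both sides (clipped to the
#' chromosome) so the signal of both arms lies inside the reported span. The
#' cluster midpoint is the basepair with the highest balance (ties:
#' leftmost); the score is the pooled signal summed over both strands across
#' the span.
#'
#' @inheritParams balance_track
#' @param cutoff Balance cutoff in `(sqrt(0.5), 1]` (default 0.95). Cutoffs at
#'   or below `sqrt(0.5)` are rejected: the single-arm skip used when scoring
#'   is only semantics-preserving above that bound.
#' @param merge_gap Maximum gap (bp) between passing basepairs merged into one
#'   cluster; defaults to `window`.
#' @return Tibble of clusters: `feature_id`, `chrom`, `start`, `end`, `strand`
#'   (always `"."`), `midpoint`, `balance`, `score`.
#' @export
cluster_bidirectional <- function(pooled, window = 200, cutoff = 0.95,
                                  merge_gap = window,
                                  genome = attr(pooled, "genome")) {
  .assert(cutoff <= 1, "cutoff must be <= 1")
  .assert(cutoff > sqrt(0.5),
          "cutoff must exceed sqrt(0.5) ~ 0.707 (single-arm bound)")
  bt <- balance_track(pooled, window, skip_single_arm = TRUE, genome = genome)
  empty <- tibble(feature_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  midpoint = numeric(), balance = numeric(), score = numeric())
  pass <- dplyr::arrange(dplyr::filter(bt, .data$balance >= .env$cutoff),
                         .data$chrom, .data$pos)
  if (nrow(pass) == 0) return(empty)
  gap <- pass$pos - dplyr::lag(pass$pos) - 1
  new_grp <- pass$chrom != dplyr::lag(pass$chrom) | gap > merge_gap
  new_grp[1] <- TRUE
  pass$cluster <- cumsum(new_grp)
  bcs <- pass %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::summarise(
      chrom = .data$chrom[1],
      first = min(.data$pos), last = max(.data$pos),
      midpoint = .data$pos[which.max(.data$balance)],
      balance = max(.data$balance),
      .groups = "drop"
    )
  len <- if (is.null(genome)) rep(NA_real_, nrow(bcs)) else
    genome$length[match(bcs$chrom, genome$chrom)]
  bcs$start <- pmax(0, bcs$first - window)
  bcs$end <- bcs$last + window + 1
  bcs$end <- ifelse(is.na(len), bcs$end, pmin(len, bcs$end))
  # pooled score over the span, both strands
  bcs$score <- purrr::pmap_dbl(
    list(bcs$chrom, bcs$start, bcs$end),
    function(ch, s, e) sum(pooled$score[pooled$chrom == ch &
                                          pooled$pos >= s & pooled$pos < e])
  )
  bcs$strand <- "."
  bcs$feature_id <- sprintf("%s:%d-%d;.", bcs$chrom, as.integer(bcs$start),
                            as.integer(bcs$end))
  dplyr::arrange(bcs[, names(empty)], .data$chrom, .data$start)
}

#' Bidirectional-cluster pipeline: pool, call, quantify, support-filter
#'
#' Calls bidirectional clusters on the pooled signal, quantifies them across
#' both strands with raw counts and removes clusters failing the tag-support
#' rule (`>= min_count` tags in at least `min_samples` samples; `>=`
#' semantics, matching thresholds phrased in tags).
#'
#' @param dataset A [ctss_dataset()].
#' @param window,cutoff,merge_gap Passed to [cluster_bidirectional()].
#' @param min_count,min_samples Support rule on raw counts.
#' @return List of class `bc_result` with elements `clusters`, `expr`,
#'   `pooled`.
#' @export
bc_pipeline <- function(dataset, window = 200, cutoff = 0.95,
                        merge_gap = window, min_count = 1, min_samples = 2) {
  if (!"tpm" %in% names(dataset$ctss)) dataset <- normalize_tpm(dataset)
  pooled <- pool_ctss(dataset)
  clusters <- cluster_bidirectional(pooled, window, cutoff, merge_gap,
                                    genome = dataset$genome)
  expr <- quantify_ranges(dataset, clusters, "both-strands")
  keep <- feature_support(expr, min_count, min_samples, use_tpm = FALSE,
                          strict = FALSE)
  structure(
    list(clusters = clusters[keep, , drop = FALSE],
         expr = expr[keep, , drop = FALSE],
         pooled = pooled),
    class = "bc_result"
  )
}

#' @export
print.bc_result <- function(x, ...) {
  cat("Bidirectional clusters:", nrow(x$clusters), "clusters x",
      length(expr_samples(x$expr)), "samples\n")
  invisible(x)
}

#' @rdname bc_pipeline
#' @param x A `bc_result`.
#' @param ... Unused.
#' @export
tidy.bc_result <- function(x, ...) as_tibble(x$clusters)

#' @rdname bc_pipeline
#' @export
glance.bc_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_samples = length(expr_samples(x$expr)),
         median_balance = stats::median(x$clusters$balance))
}
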