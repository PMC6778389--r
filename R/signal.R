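#' Normalize CTSS counts to tags-per-million
#'
#' Adds a `tpm` column (`count * 1e6 / library_size`) to every CTSS entry.
#' Library sizes are the raw per-sample totals recorded at assembly, so TPM
#' always reflects sequencing depth even after [support_filter_ctss()].
#'
#' @param dataset A [ctss_dataset()].
#' @return The dataset with a `tpm` column on its CTSS table.
#' @export
normalize_tpm <- function(dataset) {
  .assert(inherits(dataset, "ctss_dataset"), "not a ctss_dataset")
  ls <- dataset$library_sizes
  .assert(all(ls > 0), "zero-size library: %s",
          paste(names(ls)[ls == 0], collapse = ", "))
  dataset$ctss$tpm <- dataset$ctss$count * 1e6 /
    unname(ls[dataset$ctss$sample])
  dataset
}

#' Filter CTSSs by sample support
#'
#' Keeps a basepair (per strand) only if at least `min_samples` samples have a
#' count of at least `min_count` there; CTSSs failing the rule are removed
#' from every sample's track. This yields a more robust pooled signal when
#' many or low-quality samples are analyzed. Idempotent.
#'
#' @param dataset A [ctss_dataset()].
#' @param min_samples Minimum number of supporting samples (>= 1).
#' @param min_count Count a sample must reach to support a CTSS (>= 1).
#' @return The filtered dataset (library sizes unchanged).
#' @export
support_filter_ctss <- function(dataset, min_samples = 2, min_count = 1) {
  .assert(inherits(dataset, "ctss_dataset"), "not a ctss_dataset")
  .assert(min_samples >= 1 && min_count >= 1, "thresholds must be >= 1")
  keep <- dataset$ctss %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) %>%
    dplyr::filter(sum(.data$count >= .env$min_count) >= .env$min_samples) %>%
    dplyr::ungroup()
  dataset$ctss <- keep
  dataset
}

#' Pool TPM-normalized signal across samples
#'
#' Sums per-sample TPM at every basepair and strand, yielding the pooled CTSS
#' signal that tag clustering and balance scoring operate on. Without prior
#' filtering the pooled total equals `n_samples * 1e6`.
#'
#' @param dataset A TPM-normalized [ctss_dataset()] (see [normalize_tpm()]).
#' @return A tibble (`chrom`, `pos`, `strand`, `score`) of class
#'   `pooled_ctss`, carrying the genome and `n_samples` as attributes.
#' @export
pool_ctss <- function(dataset) {
  .assert(inherits(dataset, "ctss_dataset"), "not a ctss_dataset")
  .assert("tpm" %in% names(dataset$ctss),
          "dataset is not TPM-normalized; run normalize_tpm() first")
  pooled <- dataset$ctss %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) %>%
    dplyr::summarise(score = sum(.data$tpm), .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
  as_pooled_track(pooled, genome = dataset$genome,
                  n_samples = length(dataset$samples))
}

#' Mark a tibble as a pooled CTSS track
#'
#' @param x Tibble with columns `chrom`, `pos`, `strand`, `score`.
#' @param genome Genome tibble (used for clipping cluster spans).
#' @param n_samples Number of samples pooled.
#' @return `x` with class `pooled_ctss` and attributes attached.
#' @export
as_pooled_track <- function(x, genome = NULL, n_samples = NA_integer_) {
  x <- as_tibble(x)
  .assert(all(c("chrom", "pos", "strand", "score") %in% names(x)),
          "pooled track needs columns chrom, pos, strand, score")
  .assert(all(x$score > 0), "pooled values must be > 0 where stored")
  structure(x, genome = genome, n_samples = n_samples,
            class = c("pooled_ctss", class(x)))
}

# ---- expression matrices ----------------------------------------------------

new_ctss_expr <- function(features, counts, samples, library_sizes) {
  .assert(identical(colnames(counts), samples), "sample order mismatch")
  out <- dplyr::bind_cols(features, as_tibble(counts))
  structure(out, samples = samples, library_sizes = library_sizes,
            class = c("ctss_expr", class(out)))
}

#' Sample columns of an expression table
#' @param x A `ctss_expr` tibble (see [quantify_ranges()]).
#' @return Character vector of sample column names, in dataset order.
#' @export
expr_samples <- function(x) {
  s <- attr(x, "samples")
  if (!is.null(s)) return(s)
  setdiff(names(x)[vapply(x, is.numeric, logical(1))], .meta_cols)
}

#' Extract the count matrix of an expression table
#' @inheritParams expr_samples
#' @return Numeric matrix (features x samples), rownames = feature ids.
#' @export
expr_counts <- function(x) {
  m <- as.matrix(as.data.frame(x)[, expr_samples(x), drop = FALSE])
  rownames(m) <- x$feature_id
  m
}

#' TPM layer of an expression table
#'
#' Scales each sample column by `1e6 / library_size`. Counts, not TPM, are
#' stored in the table itself so the raw matrix can feed differential
#' expression tools directly.
#'
#' @inheritParams expr_samples
#' @param library_sizes Named per-sample totals; defaults to the attribute
#'   recorded by [quantify_ranges()].
#' @return The same tibble with sample columns in TPM units.
#' @export
expr_tpm <- function(x, library_sizes = attr(x, "library_sizes")) {
  .assert(!is.null(library_sizes), "no library sizes available for TPM")
  smp <- expr_samples(x)
  .assert(all(smp %in% names(library_sizes)), "library sizes missing samples")
  for (s in smp) x[[s]] <- x[[s]] * 1e6 / library_sizes[[s]]
  x
}

#' Quantify expression of arbitrary ranges
#'
#' Sums raw per-sample CTSS counts inside each range, matching strand for
#' stranded ranges (`"same-strand"`) or using both strands (`"both-strands"`,
#' for bidirectional clusters).
#'
#' @param dataset A [ctss_dataset()].
#' @param ranges Tibble with `feature_id`, `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` (`"+"`/`"-"`, or `"."`/`"*"` when unstranded).
#' @param strand_mode `"same-strand"` or `"both-strands"`.
#' @return A `ctss_expr` tibble: the range metadata columns followed by one
#'   raw-count column per sample (dataset order).
#' @export
quantify_ranges <- function(dataset, ranges,
                            strand_mode = c("same-strand", "both-strands")) {
  strand_mode <- match.arg(strand_mode)
  .assert(inherits(dataset, "ctss_dataset"), "not a ctss_dataset")
  ranges <- as_tibble(ranges)
  .assert(all(c("feature_id", "chrom", "start", "end") %in% names(ranges)),
          "ranges need feature_id, chrom, start, end")
  if (!"strand" %in% names(ranges)) ranges$strand <- "."
  .assert(!anyDuplicated(ranges$feature_id), "duplicate feature ids in ranges")
  if (strand_mode == "same-strand") {
    .assert(all(ranges$strand %in% c("+", "-")),
            "same-strand mode requires stranded ranges")
  }
  len <- dataset$genome$length[match(ranges$chrom, dataset$genome$chrom)]
  .assert(!anyNA(len) && all(ranges$start >= 0 & ranges$end <= len),
          "ranges outside genome")
  ctss <- dataset$ctss
  qgr <- GenomicRanges::GRanges(
    ctss$chrom, IRanges::IRanges(ctss$pos + 1, width = 1),
    strand = ctss$strand
  )
  rstrand <- ifelse(ranges$strand %in% c("+", "-"), ranges$strand, "*")
  sgr <- GenomicRanges::GRanges(
    ranges$chrom, IRanges::IRanges(ranges$start + 1, ranges$end),
    strand = rstrand
  )
  hits <- GenomicRanges::findOverlaps(qgr, sgr,
                                      ignore.strand = strand_mode == "both-strands")
  counts <- matrix(0, nrow = nrow(ranges), ncol = length(dataset$samples),
                   dimnames = list(ranges$feature_id, dataset$samples))
  if (length(hits) > 0) {
    agg <- tibble(
      feature = S4Vectors::subjectHits(hits),
      sample = ctss$sample[S4Vectors::queryHits(hits)],
      count = ctss$count[S4Vectors::queryHits(hits)]
    ) %>%
      dplyr::group_by(.data$feature, .data$sample) %>%
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    counts[cbind(agg$feature, match(agg$sample, dataset$samples))] <- agg$count
  }
  new_ctss_expr(ranges, counts, dataset$samples, dataset$library_sizes)
}

#' Flag features passing an expression-support rule
#'
#' A feature passes when its value exceeds `min_value` in at least
#' `min_samples` samples. `use_tpm = TRUE` evaluates the rule on the TPM layer
#' (for thresholds phrased in TPM), otherwise on raw counts (for thresholds
#' phrased in tags). `strict = TRUE` uses `>` (e.g. "> 1 TPM"); `strict =
#' FALSE` uses `>=` (e.g. ">= 1 tag").
#'
#' @param x A `ctss_expr` tibble.
#' @param min_value Expression threshold (>= 0).
#' @param min_samples Number of samples that must pass (>= 0).
#' @param use_tpm Evaluate on the TPM layer instead of raw counts.
#' @param strict Use strict inequality on the value.
#' @return Logical vector named by feature id.
#' @export
feature_support <- function(x, min_value, min_samples, use_tpm = FALSE,
                            strict = TRUE) {
  .assert(min_value >= 0 && min_samples >= 0, "thresholds must be >= 0")
  m <- if (use_tpm) expr_counts(expr_tpm(x)) else expr_counts(x)
  pass <- if (strict) m > min_value else m >= min_value
  stats::setNames(rowSums(pass) >= min_samples, x$feature_id)
}

#' @export
`[.ctss_expr` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "samples") <- attr(x, "samples")
    attr(out, "library_sizes") <- attr(x, "library_sizes")
    if (!inherits(out, "ctss_expr")) class(out) <- c("ctss_expr", class(out))
  }
  out
}
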