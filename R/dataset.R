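#' Construct a multi-sample CTSS dataset
#'
#' A CTSS dataset bundles the sparse per-bp stranded counts of all samples
#' with the genome they live on. The sample order is fixed at construction and
#' reused by every downstream expression matrix.
#'
#' @param ctss Tibble with columns `chrom`, `pos` (0-based), `strand`
#'   (`"+"`/`"-"`), `sample`, `count` (positive integers). An optional `tpm`
#'   column (added by [normalize_tpm()]) is carried along.
#' @param genome Genome tibble (see [read_genome()]).
#' @param samples Character vector fixing the sample order; defaults to order
#'   of appearance in `ctss`.
#' @param library_sizes Optional named vector of raw per-sample tag totals;
#'   computed from `ctss` when missing. Kept separately so TPM normalization
#'   still reflects sequencing depth after CTSSs have been filtered out.
#' @return An object of class `ctss_dataset`: a list with elements `ctss`,
#'   `genome`, `samples`, `library_sizes`.
#' @export
ctss_dataset <- function(ctss, genome, samples = NULL, library_sizes = NULL) {
  ctss <- as_tibble(ctss)
  need <- c("chrom", "pos", "strand", "sample", "count")
  .assert(all(need %in% names(ctss)),
          "ctss needs columns %s", paste(need, collapse = ", "))
  genome <- genome(genome)
  .assert(all(ctss$strand %in% c("+", "-")), "strand must be '+' or '-'")
  .assert(all(ctss$count > 0), "stored CTSS counts must be > 0 (sparse: absent = 0)")
  len <- genome$length[match(ctss$chrom, genome$chrom)]
  .assert(!anyNA(len), "CTSS on chromosome absent from genome")
  .assert(all(ctss$pos >= 0 & ctss$pos < len), "CTSS position outside genome")
  .assert(all(ctss$pos == round(ctss$pos)), "CTSS positions must be integral")
  if (is.null(samples)) samples <- unique(ctss$sample)
  .assert(!anyDuplicated(samples), "duplicate sample id")
  .assert(all(ctss$sample %in% samples), "ctss has samples not in sample order")
  if (is.null(library_sizes)) {
    tot <- dplyr::summarise(dplyr::group_by(ctss, .data$sample),
                            n = sum(.data$count), .groups = "drop")
    library_sizes <- stats::setNames(rep(0, length(samples)), samples)
    library_sizes[tot$sample] <- tot$n
  } else {
    .assert(all(samples %in% names(library_sizes)),
            "library_sizes must cover all samples")
    library_sizes <- library_sizes[samples]
  }
  if (any(library_sizes == 0)) {
    warning("sample(s) with zero tags: ",
            paste(samples[library_sizes == 0], collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      ctss = dplyr::arrange(ctss, .data$chrom, .data$pos, .data$strand,
                            match(.data$sample, samples)),
      genome = genome,
      samples = samples,
      library_sizes = library_sizes
    ),
    class = "ctss_dataset"
  )
}

#' Assemble a CTSS dataset from a sample sheet
#'
#' Reads every sample's plus/minus track pair, validates them against a common
#' genome and reports per-sample library sizes (total tag counts).
#'
#' @param sheet Sample sheet tibble (see [read_sample_sheet()]).
#' @param genome Genome tibble.
#' @param format Track format passed to [read_ctss_pair()].
#' @param negative_minus See [read_ctss_pair()].
#' @return A [ctss_dataset()].
#' @export
assemble_dataset <- function(sheet, genome, format = c("auto", "bigwig", "bedgraph"),
                             negative_minus = FALSE) {
  format <- match.arg(format)
  .assert(nrow(sheet) >= 1, "sample sheet is empty")
  .assert(!anyDuplicated(sheet$sample), "duplicate sample id in sheet")
  tracks <- purrr::pmap(
    list(sheet$sample, sheet$plus, sheet$minus),
    function(id, plus, minus) {
      tk <- read_ctss_pair(plus, minus, genome, format, negative_minus)
      dplyr::mutate(tk, sample = id)
    }
  )
  ctss <- dplyr::bind_rows(tracks)
  ds <- ctss_dataset(ctss, genome, samples = sheet$sample)
  message("library sizes (tags): ",
          paste(sprintf("%s=%d", ds$samples, as.integer(ds$library_sizes)),
                collapse = ", "))
  ds
}

#' @export
print.ctss_dataset <- function(x, ...) {
  cat("CTSS dataset:", length(x$samples), "samples,",
      nrow(x$ctss), "stored CTSS entries,",
      nrow(x$genome), "chromosome(s)\n")
  cat("library sizes:",
      paste(sprintf("%s=%g", x$samples, x$library_sizes), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname ctss_dataset
#' @param x A `ctss_dataset`.
#' @param ... Unused.
#' @export
tidy.ctss_dataset <- function(x, ...) x$ctss

#' @rdname ctss_dataset
#' @export
glance.ctss_dataset <- function(x, ...) {
  tibble(
    n_samples = length(x$samples),
    n_ctss = nrow(x$ctss),
    total_tags = sum(x$library_sizes),
    n_chromosomes = nrow(x$genome)
  )
}

#' Per-sample library sizes
#'
#' Total raw tag count per sample (both strands), the denominator of TPM.
#' Computed on the unfiltered tracks at dataset assembly so later CTSS
#' filtering does not change the notion of sequencing depth.
#'
#' @param dataset A [ctss_dataset()].
#' @return Named numeric vector in dataset sample order.
#' @export
library_sizes <- function(dataset) {
  .assert(inherits(dataset, "ctss_dataset"), "not a ctss_dataset")
  dataset$library_sizes
}
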