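#' Write clusters as BED6
#'
#' The BED score column is the pooled cluster score rounded and capped at
#' 1000 (BED convention); the exact score belongs in the companion TSV.
#'
#' @param clusters Cluster tibble (TCs or BCs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(clusters, path) {
  sc <- pmin(1000, round(clusters$score))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   clusters$chrom, as.integer(clusters$start),
                   as.integer(clusters$end), clusters$feature_id,
                   as.integer(sc), clusters$strand)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write TC-enhancer links as BEDPE
#'
#' @param links Link tibble from [correlate_links()].
#' @param tcs,enhancers The cluster tibbles the links refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(links, tcs, enhancers, path) {
  ti <- match(links$tc_id, tcs$feature_id)
  ei <- match(links$enhancer_id, enhancers$feature_id)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\t%s\t%.6g\t%s\t%s\t%.6g\t%.6g",
    tcs$chrom[ti], as.integer(tcs$start[ti]), as.integer(tcs$end[ti]),
    enhancers$chrom[ei], as.integer(enhancers$start[ei]),
    as.integer(enhancers$end[ei]),
    paste0(links$tc_id, "|", links$enhancer_id),
    links$estimate, tcs$strand[ti], ".", links$p_value, links$p_adj
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write an expression table as TSV
#'
#' Feature metadata columns first, then one raw-count column per sample.
#'
#' @param x A `ctss_expr` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Write any result tibble as TSV (list columns collapsed with commas)
#' @param x Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  x <- as_tibble(x)
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      x[[col]] <- vapply(x[[col]], paste, character(1), collapse = ",")
    }
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
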