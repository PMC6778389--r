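#' Read a chromosome-sizes file
#'
#' Reads a two-column (name, length) tab-separated file describing the genome
#' the CTSS tracks live on. All coordinates in capclust are 0-based half-open,
#' so valid positions on a chromosome of length `L` are `0 .. L-1`.
#'
#' @param path Path to a chrom-sizes text file (no header).
#' @return A tibble with columns `chrom` (character) and `length` (integer bp).
#' @export
read_genome <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  .assert(ncol(raw) >= 2, "chrom-sizes file '%s' needs two columns", path)
  genome(tibble(chrom = as.character(raw[[1]]), length = as.numeric(raw[[2]])))
}

#' Construct/validate a genome table
#'
#' @param x A data frame with columns `chrom` and `length`.
#' @return A validated tibble with columns `chrom` and `length`.
#' @export
genome <- function(x) {
  x <- as_tibble(x)
  .assert(all(c("chrom", "length") %in% names(x)),
          "genome needs columns 'chrom' and 'length'")
  x$chrom <- as.character(x$chrom)
  x$length <- as.numeric(x$length)
  .assert(!anyDuplicated(x$chrom), "duplicated chromosome names in genome")
  .assert(all(x$length > 0), "chromosome lengths must be positive")
  x[, c("chrom", "length")]
}

#' Read a sample sheet
#'
#' The sample sheet is a TSV with header columns `sample`, `plus`, `minus` and
#' an optional `group`, giving for every library the paths to its plus- and
#' minus-strand CTSS tracks.
#'
#' @param path Path to the sample-sheet TSV.
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .assert(all(c("sample", "plus", "minus") %in% names(sheet)),
          "sample sheet needs columns 'sample', 'plus', 'minus'")
  .assert(!anyDuplicated(sheet$sample), "duplicated sample ids in sample sheet")
  .assert(!anyNA(sheet$plus) && !anyNA(sheet$minus),
          "both track paths must be present for every sample")
  sheet
}

.guess_format <- function(path) {
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) return("bigwig")
  if (grepl("\\.(bedgraph|bg|bdg)$", path, ignore.case = TRUE)) return("bedgraph")
  stop("cannot guess track format from extension of '", path,
       "'; pass format explicitly", call. = FALSE)
}

# Expand run-length intervals (0-based half-open) to one row per bp.
.expand_perbp <- function(chrom, start, end, value) {
  w <- end - start
  idx <- rep.int(seq_along(w), w)
  tibble(
    chrom = chrom[idx],
    pos = start[idx] + (sequence(w) - 1),
    value = value[idx]
  )
}

.check_genome_chroms <- function(chroms, lengths, genome, path) {
  known <- match(chroms, genome$chrom)
  if (anyNA(known)) {
    warning("track '", path, "' has chromosomes absent from the genome (",
            paste(unique(chroms[is.na(known)]), collapse = ", "),
            "); their signal is dropped", call. = FALSE)
  }
  ok <- !is.na(known)
  if (!is.null(lengths)) {
    bad <- ok & lengths != genome$length[known]
    .assert(!any(bad),
            "genome mismatch for '%s': declared length of %s differs from genome",
            path, paste(chroms[bad], collapse = ", "))
  }
  ok
}

.read_track_bigwig <- function(path, genome) {
  .assert(file.exists(path), "track file '%s' does not exist", path)
  gr <- rtracklayer::import.bw(path)
  sl <- GenomeInfoDb::seqlengths(gr)
  keep_chrom <- .check_genome_chroms(names(sl), unname(sl), genome, path)
  gr <- gr[as.character(GenomeInfoDb::seqnames(gr)) %in% names(sl)[keep_chrom]]
  out <- .expand_perbp(as.character(GenomeInfoDb::seqnames(gr)),
                       BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                       S4Vectors::mcols(gr)$score)
  dplyr::filter(out, .data$value != 0)
}

.read_track_bedgraph <- function(path, genome) {
  .assert(file.exists(path), "track file '%s' does not exist", path)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), pos = numeric(), value = numeric()))
  }
  tab <- readr::read_tsv(I(lines), col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", progress = FALSE)
  .assert(!anyNA(tab$start) && !anyNA(tab$end) && !anyNA(tab$value),
          "malformed bedGraph line in '%s'", path)
  .assert(all(tab$start >= 0 & tab$end > tab$start),
          "bedGraph '%s': intervals must satisfy 0 <= start < end", path)
  keep_chrom <- .check_genome_chroms(unique(tab$chrom), NULL, genome, path)
  tab <- tab[tab$chrom %in% unique(tab$chrom)[keep_chrom], , drop = FALSE]
  len <- genome$length[match(tab$chrom, genome$chrom)]
  .assert(all(tab$end <= len),
          "bedGraph '%s': interval beyond chromosome length", path)
  tab <- dplyr::arrange(tab, .data$chrom, .data$start)
  by_chrom <- split(tab, tab$chrom)
  for (ch in by_chrom) {
    n <- nrow(ch)
    .assert(n < 2 || all(ch$start[-1] >= ch$end[-n]),
            "bedGraph '%s': overlapping intervals on %s", path, ch$chrom[1])
  }
  out <- .expand_perbp(tab$chrom, tab$start, tab$end, tab$value)
  dplyr::filter(out, .data$value != 0)
}

#' Read a single per-bp track
#'
#' Low-level reader returning a per-bp tibble from a BigWig or bedGraph file;
#' run-length intervals are expanded to one row per basepair and zero values
#' dropped. Values are returned as-is (no integer check); use
#' [read_ctss_pair()] for CTSS count tracks.
#'
#' @param path Track file path.
#' @param genome Genome tibble from [read_genome()].
#' @param format `"auto"` (by extension), `"bigwig"` or `"bedgraph"`.
#' @return Tibble with columns `chrom`, `pos` (0-based) and `value`.
#' @export
read_track <- function(path, genome, format = c("auto", "bigwig", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  out <- switch(format,
    bigwig = .read_track_bigwig(path, genome),
    bedgraph = .read_track_bedgraph(path, genome)
  )
  dplyr::arrange(out, .data$chrom, .data$pos)
}

.as_counts <- function(track, path, strand, negative_minus) {
  if (any(track$value < 0)) {
    if (strand == "-" && negative_minus) {
      track$value <- abs(track$value)
    } else {
      stop("format error in '", path, "': negative count on ", strand,
           " strand track (set negative_minus = TRUE for tracks that encode ",
           "minus signal as negative values)", call. = FALSE)
    }
  }
  off <- abs(track$value - round(track$value))
  .assert(all(off <= 1e-6),
          "format error in '%s': non-integer count beyond tolerance", path)
  track$value <- round(track$value)
  dplyr::filter(track, .data$value > 0)
}

#' Read a plus/minus pair of CTSS count tracks
#'
#' Reads a per-sample pair of per-bp CTSS tracks (counts of tag 5' ends per
#' basepair) and returns them as a single stranded sparse tibble. Values must
#' be non-negative integers (within 1e-6); minus-strand tracks using the
#' negative-value convention are accepted with `negative_minus = TRUE`.
#'
#' @param plus_path,minus_path Paths to the plus/minus strand tracks.
#' @param genome Genome tibble from [read_genome()].
#' @param format `"auto"`, `"bigwig"` or `"bedgraph"`.
#' @param negative_minus Take absolute values on the minus track.
#' @return Tibble with columns `chrom`, `pos`, `strand`, `count`.
#' @export
read_ctss_pair <- function(plus_path, minus_path, genome,
                           format = c("auto", "bigwig", "bedgraph"),
                           negative_minus = FALSE) {
  format <- match.arg(format)
  plus <- .as_counts(read_track(plus_path, genome, format), plus_path, "+",
                     negative_minus)
  minus <- .as_counts(read_track(minus_path, genome, format), minus_path, "-",
                      negative_minus)
  out <- dplyr::bind_rows(
    dplyr::mutate(plus, strand = "+"),
    dplyr::mutate(minus, strand = "-")
  )
  out <- dplyr::rename(out, count = "value")
  dplyr::arrange(out[, c("chrom", "pos", "strand", "count")],
                 .data$chrom, .data$pos, .data$strand)
}

# Collapse a sorted per-bp tibble (chrom, pos, value) into run-length rows.
.runs <- function(track) {
  track <- dplyr::arrange(track, .data$chrom, .data$pos)
  brk <- track$chrom != dplyr::lag(track$chrom) |
    track$pos != dplyr::lag(track$pos) + 1 |
    track$value != dplyr::lag(track$value)
  brk[1] <- TRUE
  track$run <- cumsum(brk)
  dplyr::summarise(dplyr::group_by(track, .data$run),
                   chrom = .data$chrom[1],
                   start = min(.data$pos), end = max(.data$pos) + 1,
                   value = .data$value[1], .groups = "drop")[, -1]
}

#' Write a per-bp track to BigWig or bedGraph
#'
#' Adjacent basepairs with equal values are merged into run-length intervals.
#' Integer counts round-trip exactly; fractional values (pooled TPM) are
#' written with six decimals in bedGraph.
#'
#' @param track Tibble with `chrom`, `pos` and a value column (`score`, `tpm`
#'   or `count`; the first present is used unless `value` names one). If the
#'   tibble has a `strand` column with both strands, pick one with `strand`.
#' @param path Output path.
#' @param format `"auto"`, `"bigwig"` or `"bedgraph"`.
#' @param value Name of the value column to write.
#' @param strand Optional strand to select from a stranded track.
#' @param genome Genome tibble; required for BigWig output (declares lengths).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("auto", "bigwig", "bedgraph"),
                        value = NULL, strand = NULL,
                        genome = attr(track, "genome")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!is.null(strand) && "strand" %in% names(track)) {
    track <- dplyr::filter(track, .data$strand == .env$strand)
  }
  if ("strand" %in% names(track)) {
    .assert(length(unique(track$strand)) <= 1,
            "track has both strands; select one with strand = '+'/'-'")
  }
  if (is.null(value)) {
    value <- intersect(c("score", "tpm", "count", "value"), names(track))[1]
    .assert(!is.na(value), "no value column found in track")
  }
  tk <- tibble(chrom = track$chrom, pos = track$pos, value = track[[value]])
  if (!is.null(genome)) {
    len <- genome$length[match(tk$chrom, genome$chrom)]
    .assert(!anyNA(len) && all(tk$pos >= 0 & tk$pos < len),
            "track positions outside genome")
  }
  runs <- if (nrow(tk) > 0) .runs(tk) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           value = numeric())
  if (format == "bedgraph") {
    txt <- if (nrow(runs) == 0) character() else {
      vals <- if (all(runs$value == round(runs$value))) {
        sprintf("%d", as.integer(runs$value))
      } else {
        sprintf("%.6f", runs$value)
      }
      sprintf("%s\t%d\t%d\t%s", runs$chrom, as.integer(runs$start),
              as.integer(runs$end), vals)
    }
    readr::write_lines(c("track type=bedGraph", txt), path)
  } else {
    .assert(!is.null(genome), "BigWig output needs a genome (for lengths)")
    .assert(nrow(runs) > 0,
            "the BigWig format cannot hold an empty track; use bedGraph")
    sl <- stats::setNames(as.integer(genome$length), genome$chrom)
    gr <- GenomicRanges::GRanges(
      seqnames = runs$chrom,
      ranges = IRanges::IRanges(start = runs$start + 1, end = runs$end),
      score = runs$value,
      seqlengths = sl
    )
    rtracklayer::export.bw(gr, path)
  }
  invisible(path)
}
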