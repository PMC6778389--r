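# Independent oracles and small builders used across the suite.

tiny_genome <- function(len = 1e5, chrom = "chr1") {
  tibble::tibble(chrom = chrom, length = len)
}

# Build a dataset from a compact spec: list(sample = list(`+` = c(pos = count), ...))
make_dataset <- function(spec, genome = tiny_genome()) {
  rows <- list()
  for (smp in names(spec)) {
    for (st in names(spec[[smp]])) {
      v <- spec[[smp]][[st]]
      if (length(v) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = genome$chrom[1], pos = as.numeric(names(v)), strand = st,
        sample = smp, count = as.numeric(v)
      )
    }
  }
  ctss_dataset(dplyr::bind_rows(rows), genome, samples = names(spec))
}

make_pooled <- function(plus = numeric(), minus = numeric(),
                        genome = tiny_genome(), chrom = "chr1") {
  tk <- dplyr::bind_rows(
    tibble::tibble(chrom = chrom, pos = as.numeric(names(plus)),
                   strand = "+", score = as.numeric(plus)),
    tibble::tibble(chrom = chrom, pos = as.numeric(names(minus)),
                   strand = "-", score = as.numeric(minus))
  )
  as_pooled_track(tk, genome = genome, n_samples = 1L)
}

# Brute-force slice-reduce: dense scan over maximal runs of surviving bps.
oracle_slice_reduce <- function(pooled, threshold, merge_dist) {
  out <- list()
  df <- as.data.frame(pooled)
  for (ch in unique(df$chrom)) for (st in c("+", "-")) {
    tk <- df[df$chrom == ch & df$strand == st & df$score >= threshold, ]
    if (nrow(tk) == 0) next
    tk <- tk[order(tk$pos), ]
    lo <- min(tk$pos); hi <- max(tk$pos)
    dense <- numeric(hi - lo + 1)
    dense[tk$pos - lo + 1] <- tk$score
    keep <- dense > 0
    cl_id <- 0; gap <- Inf; assign <- integer(length(dense))
    for (i in seq_along(dense)) {
      if (keep[i]) {
        if (gap > merge_dist) cl_id <- cl_id + 1
        assign[i] <- cl_id; gap <- 0
      } else gap <- gap + 1
    }
    for (cl in seq_len(cl_id)) {
      idx <- which(assign == cl)
      pos <- idx + lo - 1
      sc <- dense[idx]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = min(pos), end = max(pos) + 1, strand = st,
        peak = pos[which.max(sc)], peak_value = max(sc), score = sum(sc)
      )
    }
  }
  if (length(out) == 0) return(NULL)
  res <- dplyr::arrange(dplyr::bind_rows(out), chrom, start, strand)
  res$feature_id <- sprintf("%s:%d-%d;%s", res$chrom, as.integer(res$start),
                            as.integer(res$end), res$strand)
  res[, c("feature_id", "chrom", "start", "end", "strand", "peak",
          "peak_value", "score")]
}

random_sparse_track <- function(max_len = 10000, n_max = 60) {
  n <- sample(0:n_max, 1)
  if (n == 0) return(make_pooled())
  pos <- sample.int(max_len, n) - 1
  st <- sample(c("+", "-"), n, replace = TRUE)
  tk <- tibble::tibble(chrom = "chr1", pos = pos, strand = st,
                       score = round(stats::rexp(n, 2), 3) + 0.001)
  as_pooled_track(dplyr::arrange(tk, pos, strand),
                  genome = tiny_genome(max_len), n_samples = 1L)
}

# Bhattacharyya coefficient computed the long way.
oracle_balance <- function(arms) {
  q <- c(0, 0.5, 0, 0.5)  # (PU, PD, MU, MD) ideal
  f <- arms / sum(arms)
  sum(sqrt(f * q))
}

# Kendall tau-b by exhaustive pair counting.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# First-crossing interquantile width computed independently.
oracle_iqr <- function(pos, score, lower, upper) {
  o <- order(pos)
  pos <- pos[o]; score <- score[o]
  cum <- cumsum(score) / sum(score)
  pos[which(cum >= upper)[1]] - pos[which(cum >= lower)[1]] + 1
}

write_bedgraph_file <- function(lines, path = tempfile(fileext = ".bedgraph")) {
  writeLines(lines, path)
  path
}

mk_expr <- function(counts, samples = paste0("s", seq_len(ncol(counts)))) {
  structure(
    dplyr::bind_cols(tibble::tibble(feature_id = rownames(counts)),
                     tibble::as_tibble(`colnames<-`(counts, samples))),
    samples = samples,
    class = c("ctss_expr", "tbl_df", "tbl", "data.frame")
  )
}
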