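#' Transcript models for cluster annotation
#'
#' Builds the indexed transcript-model object used by [annotate_clusters()]
#' and [assign_genes()] from exon (and optionally CDS) intervals. Derived per
#' transcript: the annotated TSS (strand-aware 5' end), the transcript span,
#' and the 5'/3' UTRs (exonic sequence minus CDS on the respective side).
#' All coordinates are 0-based half-open.
#'
#' @param exons Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `tx_id`, `gene_id`.
#' @param cds Optional tibble with the same columns for coding sequence.
#' @return An object of class `tx_models`: list with tibbles `transcripts`
#'   (`tx_id`, `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`), `genes`
#'   (span union per gene), `exons`, `cds`, `utr5`, `utr3`.
#' @export
tx_models <- function(exons, cds = NULL) {
  exons <- as_tibble(exons)
  need <- c("chrom", "start", "end", "strand", "tx_id", "gene_id")
  .assert(all(need %in% names(exons)),
          "exons need columns %s", paste(need, collapse = ", "))
  .assert(all(exons$strand %in% c("+", "-")), "exon strand must be '+'/'-'")
  .assert(all(exons$start >= 0 & exons$end > exons$start),
          "malformed exon coordinates")
  if (is.null(cds)) cds <- exons[0, ]
  cds <- as_tibble(cds)

  if (nrow(exons) == 0) {
    empty_tx <- tibble(tx_id = character(), gene_id = character(),
                       chrom = character(), strand = character(),
                       start = numeric(), end = numeric(), tss = numeric())
    return(structure(
      list(transcripts = empty_tx,
           genes = empty_tx[, c("gene_id", "chrom", "strand", "start", "end")],
           exons = exons[, need], cds = exons[, need],
           utr5 = exons[, need], utr3 = exons[, need]),
      class = "tx_models"
    ))
  }

  transcripts <- exons %>%
    dplyr::group_by(.data$tx_id) %>%
    dplyr::summarise(
      gene_id = .data$gene_id[1], chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    ) %>%
    dplyr::mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1))

  genes <- transcripts %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(chrom = .data$chrom[1], strand = .data$strand[1],
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop")

  # UTRs: per transcript with CDS, exonic sequence outside the CDS span,
  # split by which side of the CDS it falls on relative to strand.
  utr <- NULL
  if (nrow(cds) > 0) {
    cds_span <- cds %>%
      dplyr::group_by(.data$tx_id) %>%
      dplyr::summarise(cstart = min(.data$start), cend = max(.data$end),
                       .groups = "drop")
    ex <- dplyr::inner_join(exons, cds_span, by = "tx_id")
    left <- ex %>%
      dplyr::mutate(end = pmin(.data$end, .data$cstart)) %>%
      dplyr::filter(.data$end > .data$start)
    right <- ex %>%
      dplyr::mutate(start = pmax(.data$start, .data$cend)) %>%
      dplyr::filter(.data$end > .data$start)
    utr <- dplyr::bind_rows(
      dplyr::mutate(left, side = ifelse(.data$strand == "+", "5", "3")),
      dplyr::mutate(right, side = ifelse(.data$strand == "+", "3", "5"))
    )
    utr <- utr[, c(need, "side")]
  } else {
    utr <- dplyr::mutate(exons[0, need], side = character(0))
  }

  structure(
    list(
      transcripts = transcripts,
      genes = genes,
      exons = exons[, need],
      cds = if (nrow(cds) > 0) cds[, need] else exons[0, need],
      utr5 = dplyr::select(dplyr::filter(utr, .data$side == "5"), -"side"),
      utr3 = dplyr::select(dplyr::filter(utr, .data$side == "3"), -"side")
    ),
    class = "tx_models"
  )
}

#' @export
print.tx_models <- function(x, ...) {
  cat("Transcript models:", nrow(x$transcripts), "transcripts,",
      nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Load transcript models from a GTF/GFF3 file
#'
#' Imports `exon` and `CDS` features carrying `transcript_id` and `gene_id`
#' attributes and converts the 1-based inclusive GTF coordinates to the
#' internal 0-based half-open convention.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A [tx_models()] object.
#' @export
load_models <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  .assert(all(c("type", "transcript_id", "gene_id") %in% names(mc)),
          "GTF/GFF3 '%s' must carry type, transcript_id and gene_id", path)
  keep <- as.character(mc$type) %in% c("exon", "CDS")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  tab <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,   # GTF is 1-based inclusive
    end = as.numeric(BiocGenerics::end(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    tx_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    type = as.character(mc$type)
  )
  .assert(!anyNA(tab$tx_id) && !anyNA(tab$gene_id),
          "GTF '%s': exon/CDS features missing transcript_id or gene_id", path)
  .assert(all(tab$strand %in% c("+", "-")),
          "GTF '%s': exon features must be stranded", path)
  tx_models(tab[tab$type == "exon", -7], cds = tab[tab$type == "CDS", -7])
}

#' Write transcript models as GTF
#'
#' @param models A [tx_models()] object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_models_gtf <- function(models, path) {
  feats <- dplyr::bind_rows(
    dplyr::mutate(models$exons, type = "exon"),
    dplyr::mutate(models$cds, type = "CDS")
  )
  gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start + 1, feats$end),
    strand = feats$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "capclust", type = feats$type,
    transcript_id = feats$tx_id, gene_id = feats$gene_id
  )
  # rtracklayer warns that CDS features lack phase; irrelevant here
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}

.default_categories <- c("promoter", "proximal", "fiveUTR", "threeUTR",
                         "CDS", "exon", "intron", "antisense", "intergenic")

.gr0 <- function(chrom, start, end, strand) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                         strand = strand)
}

# Category interval sets, one GRanges per category (except intergenic).
.category_ranges <- function(models, promoter_radius, proximal_dist) {
  tx <- models$transcripts
  tss1 <- tx$tss + 1  # 1-based
  tssgr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tss1, tss1),
                                  strand = tx$strand)
  list(
    promoter = GenomicRanges::trim(suppressWarnings(
      GenomicRanges::resize(tssgr, width = 2 * promoter_radius + 1,
                            fix = "center"))),
    proximal = GenomicRanges::trim(suppressWarnings(
      GenomicRanges::flank(tssgr, width = proximal_dist, start = TRUE))),
    fiveUTR = .gr0(models$utr5$chrom, models$utr5$start, models$utr5$end,
                   models$utr5$strand),
    threeUTR = .gr0(models$utr3$chrom, models$utr3$start, models$utr3$end,
                    models$utr3$strand),
    CDS = .gr0(models$cds$chrom, models$cds$start, models$cds$end,
               models$cds$strand),
    exon = .gr0(models$exons$chrom, models$exons$start, models$exons$end,
                models$exons$strand),
    intron = .gr0(tx$chrom, tx$start, tx$end, tx$strand),
    antisense = .gr0(tx$chrom, tx$start, tx$end, tx$strand)
  )
}

.cluster_anchor <- function(clusters) {
  if ("peak" %in% names(clusters) && !anyNA(clusters$peak)) return(clusters$peak)
  if ("midpoint" %in% names(clusters)) return(clusters$midpoint)
  floor((clusters$start + clusters$end - 1) / 2)
}

#' Hierarchically annotate clusters against transcript models
#'
#' Assigns each cluster exactly one annotation category by testing its anchor
#' basepair (TC peak; BC max-balance position) against every transcript and
#' keeping the highest-priority match. The default priority order is
#' promoter, proximal, fiveUTR, threeUTR, CDS, exon, intron, antisense,
#' intergenic (highest first), reflecting that a cluster at an annotated TSS is more likely
#' an annotated promoter than, say, a novel intragenic one. Stranded clusters
#' match same-strand transcripts for all categories except `antisense`
#' (overlap with an opposite-strand transcript only); unstranded clusters
#' (strand `"."`) match either strand and can never be antisense. No overlap
#' at all gives `intergenic`.
#'
#' @param clusters Cluster tibble from [cluster_unidirectional()] or
#'   [cluster_bidirectional()].
#' @param models A [tx_models()] object.
#' @param promoter_radius Promoter = within this many bp of an annotated TSS
#'   (default 100, i.e. +/-100 bp).
#' @param proximal_dist Proximal = up to this many bp upstream of a TSS
#'   (default 1000).
#' @param categories Category priority order; a permutation or subset of the
#'   default vector (`intergenic` is always the fallback).
#' @return `clusters` with a `category` factor column (levels = priority
#'   order).
#' @export
annotate_clusters <- function(clusters, models, promoter_radius = 100,
                              proximal_dist = 1000,
                              categories = NULL) {
  if (is.null(categories)) categories <- .default_categories
  .assert(all(categories %in% .default_categories),
          "unknown category; available: %s",
          paste(.default_categories, collapse = ", "))
  categories <- union(categories, "intergenic")
  clusters <- as_tibble(clusters)
  if (nrow(clusters) == 0) {
    clusters$category <- factor(character(), levels = categories)
    return(clusters)
  }
  anchor <- .cluster_anchor(clusters)
  stranded <- clusters$strand %in% c("+", "-")
  agr <- GenomicRanges::GRanges(
    clusters$chrom, IRanges::IRanges(anchor + 1, width = 1),
    strand = ifelse(stranded, clusters$strand, "*")
  )
  cr <- .category_ranges(models, promoter_radius, proximal_dist)
  cat <- rep("intergenic", nrow(clusters))
  for (nm in rev(setdiff(categories, "intergenic"))) {
    if (nm == "antisense") {
      inv <- agr
      BiocGenerics::strand(inv) <- ifelse(clusters$strand == "+", "-",
                                          ifelse(clusters$strand == "-", "+", "*"))
      hit <- IRanges::overlapsAny(inv, cr[[nm]]) & stranded
    } else {
      hit <- IRanges::overlapsAny(agr, cr[[nm]])
    }
    cat[hit] <- nm
  }
  clusters$category <- factor(cat, levels = categories)
  clusters
}

#' Select enhancer candidates from bidirectional clusters
#'
#' Keeps bidirectional clusters annotated as `intron` or `intergenic` —
#' equivalently, drops any cluster whose span overlaps exonic sequence (on
#' either strand) or whose midpoint lies in the promoter/proximal zone
#' (within `proximal_dist` upstream or `promoter_radius` of an annotated
#' TSS). Bidirectional clusters at gene promoters or over exons are commonly
#' bidirectionally transcribed without being enhancers, so they are filtered
#' away. Exon overlap is tested on the whole span (exon contamination is a
#' span property) while the promoter zone is tested at the midpoint.
#'
#' @param bcs Bidirectional-cluster tibble (see [cluster_bidirectional()]).
#' @inheritParams annotate_clusters
#' @return The retained clusters with their `category` column (`intron` or
#'   `intergenic`).
#' @export
select_enhancer_candidates <- function(bcs, models, promoter_radius = 100,
                                       proximal_dist = 1000) {
  ann <- annotate_clusters(bcs, models, promoter_radius, proximal_dist)
  keep <- ann$category %in% c("intron", "intergenic")
  if (any(keep)) {
    span <- .gr0(ann$chrom, ann$start, ann$end, "*")
    exonic <- IRanges::overlapsAny(
      span, .gr0(models$exons$chrom, models$exons$start, models$exons$end, "*"),
      ignore.strand = TRUE
    )
    keep <- keep & !exonic
  }
  droplevels(ann[keep, , drop = FALSE])
}

#' Assign tag clusters to genes
#'
#' A TC is assigned to a gene when its peak lies within the gene's span (the
#' union of its transcripts) extended upstream by `proximal_dist`, on the
#' same strand. When several genes match, the gene whose nearest annotated
#' TSS is closest to the peak wins; exact ties leave the TC unassigned.
#'
#' @param tcs Stranded cluster tibble (see [cluster_unidirectional()]).
#' @param models A [tx_models()] object.
#' @param proximal_dist Upstream extension of gene spans in bp.
#' @return Tibble with columns `feature_id`, `gene_id` (`NA` = unassigned).
#' @export
assign_genes <- function(tcs, models, proximal_dist = 1000) {
  tcs <- as_tibble(tcs)
  .assert(all(tcs$strand %in% c("+", "-")), "TCs must be stranded")
  if (nrow(tcs) == 0) return(tibble(feature_id = character(), gene_id = character()))
  g <- models$genes
  ext_start <- ifelse(g$strand == "+", pmax(0, g$start - proximal_dist), g$start)
  ext_end <- ifelse(g$strand == "+", g$end, g$end + proximal_dist)
  ggr <- .gr0(g$chrom, ext_start, ext_end, g$strand)
  peak <- tcs$peak
  pgr <- GenomicRanges::GRanges(tcs$chrom,
                                IRanges::IRanges(peak + 1, width = 1),
                                strand = tcs$strand)
  hits <- GenomicRanges::findOverlaps(pgr, ggr)
  if (length(hits) == 0) {
    return(tibble(feature_id = tcs$feature_id, gene_id = NA_character_))
  }
  cand <- tibble(
    idx = S4Vectors::queryHits(hits),
    gene_id = g$gene_id[S4Vectors::subjectHits(hits)]
  ) %>%
    dplyr::left_join(
      models$transcripts[, c("gene_id", "tss")],
      by = "gene_id", relationship = "many-to-many"
    ) %>%
    dplyr::mutate(dist = abs(peak[.data$idx] - .data$tss)) %>%
    dplyr::group_by(.data$idx, .data$gene_id) %>%
    dplyr::summarise(dist = min(.data$dist), .groups = "drop") %>%
    dplyr::group_by(.data$idx) %>%
    dplyr::summarise(
      gene_id = if (sum(.data$dist == min(.data$dist)) > 1) NA_character_
                else .data$gene_id[which.min(.data$dist)],
      .groups = "drop"
    )
  out <- tibble(feature_id = tcs$feature_id, gene_id = NA_character_)
  out$gene_id[cand$idx] <- cand$gene_id
  out
}

#' Sum tag-cluster counts into a gene-level expression matrix
#'
#' @param tc_expr A `ctss_expr` table of TC counts (see [quantify_ranges()]).
#' @param assignment Tibble from [assign_genes()]. Unassigned TCs are
#'   excluded, so the gene matrix total equals the total counts of assigned
#'   TCs.
#' @return A `ctss_expr` tibble with `feature_id` = gene id.
#' @export
gene_matrix <- function(tc_expr, assignment) {
  smp <- expr_samples(tc_expr)
  joined <- dplyr::inner_join(
    dplyr::filter(assignment, !is.na(.data$gene_id)),
    as_tibble(tc_expr)[, c("feature_id", smp)],
    by = "feature_id"
  )
  out <- joined %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(smp), sum), .groups = "drop") %>%
    dplyr::rename(feature_id = "gene_id")
  new_ctss_expr(out[, "feature_id"],
                as.matrix(as.data.frame(out)[, smp, drop = FALSE]),
                smp, attr(tc_expr, "library_sizes"))
}

#' Composition filter for alternative TSS candidates
#'
#' For every gene-assigned TC, computes per sample the fraction of the gene's
#' total expression contributed by the TC; a TC is kept when its fraction
#' exceeds `min_fraction` in more than `min_samples` samples (samples where
#' the gene total is zero count as failing). Unassigned TCs are kept
#' unconditionally. This removes lowly-expressed alternative TSS candidates
#' that contribute e.g. less than 10% of their gene's expression.
#'
#' @param tc_expr A `ctss_expr` table of TC counts.
#' @param assignment Tibble from [assign_genes()].
#' @param min_fraction Minimum fraction of gene expression (strictly
#'   exceeded; default 0.1).
#' @param min_samples Number of samples that must strictly exceed it
#'   (strictly more than this many; default 0, i.e. at least one sample).
#' @return Tibble `feature_id`, `gene_id`, `n_above` (samples passing),
#'   `keep`.
#' @export
composition_filter <- function(tc_expr, assignment, min_fraction = 0.1,
                               min_samples = 0) {
  m <- expr_counts(tc_expr)
  gene <- assignment$gene_id[match(rownames(m), assignment$feature_id)]
  out <- tibble(feature_id = rownames(m), gene_id = gene,
                n_above = NA_integer_, keep = TRUE)
  assigned <- !is.na(gene)
  if (any(assigned)) {
    totals <- rowsum(m[assigned, , drop = FALSE], gene[assigned])
    frac <- m[assigned, , drop = FALSE] / totals[gene[assigned], , drop = FALSE]
    above <- frac > min_fraction
    above[!is.finite(frac)] <- FALSE  # gene total 0 -> undefined -> fails
    out$n_above[assigned] <- as.integer(rowSums(above))
    out$keep[assigned] <- rowSums(above) > min_samples
  }
  out
}

#' Per-gene tag-cluster counts before/after the composition filter
#'
#' @param assignment Tibble from [assign_genes()].
#' @param kept_ids Feature ids surviving [composition_filter()].
#' @return Tibble `gene_id`, `n_total`, `n_kept` for every gene with at least
#'   one assigned TC.
#' @export
multi_tc_summary <- function(assignment, kept_ids) {
  assignment %>%
    dplyr::filter(!is.na(.data$gene_id)) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      n_total = dplyr::n(),
      n_kept = sum(.data$feature_id %in% kept_ids),
      .groups = "drop"
    )
}

#' Fraction of genes using more than one tag cluster
#'
#' @param summary Tibble from [multi_tc_summary()].
#' @return Tibble with `frac_multi_total` (share of genes with >1 assigned
#'   TC) and `frac_multi_kept` (same after the composition filter).
#' @export
multi_tc_fraction <- function(summary) {
  tibble(
    frac_multi_total = mean(summary$n_total > 1),
    frac_multi_kept = mean(summary$n_kept > 1)
  )
}
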