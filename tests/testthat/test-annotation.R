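# A compact two-gene model set used throughout:
#  geneA (+): tx1 exons [1000,1200) + [1800,2500), CDS [1100,2200)
#             tx2 (isoform) single exon [500,2500)  -> TSS at 500
#  geneB (-): tx3 exons [6000,6300) + [7000,7500), CDS [6100,7200), TSS 7499
demo_models <- function() {
  exons <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 1800, 500, 6000, 7000),
    end = c(1200, 2500, 2500, 6300, 7500),
    strand = c("+", "+", "+", "-", "-"),
    tx_id = c("tx1", "tx1", "tx2", "tx3", "tx3"),
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB")
  )
  cds <- tibble::tibble(
    chrom = "chr1",
    start = c(1100, 1800, 6100, 7000),
    end = c(1200, 2200, 6300, 7200),
    strand = c("+", "+", "-", "-"),
    tx_id = c("tx1", "tx1", "tx3", "tx3"),
    gene_id = c("geneA", "geneA", "geneB", "geneB")
  )
  tx_models(exons, cds)
}

tc_at <- function(peak, strand = "+", id = paste0("tc", peak)) {
  tibble::tibble(feature_id = id, chrom = "chr1", start = peak - 2,
                 end = peak + 3, strand = strand, peak = peak,
                 peak_value = 1, score = 1)
}

test_that("transcript models derive TSS, spans and UTRs with 0-based coords", {
  m <- demo_models()
  expect_equal(m$transcripts$tss[m$transcripts$tx_id == "tx1"], 1000)
  expect_equal(m$transcripts$tss[m$transcripts$tx_id == "tx3"], 7499)
  expect_equal(m$genes$start[m$genes$gene_id == "geneA"], 500)
  # tx1 5'UTR = exonic part before the CDS; 3'UTR after it
  u5 <- m$utr5[m$utr5$tx_id == "tx1", ]
  expect_equal(c(u5$start, u5$end), c(1000, 1100))
  u3 <- m$utr3[m$utr3$tx_id == "tx1", ]
  expect_equal(c(u3$start, u3$end), c(2200, 2500))
  # minus-strand transcript: 5'UTR on the right side
  u5b <- m$utr5[m$utr5$tx_id == "tx3", ]
  expect_equal(c(u5b$start, u5b$end), c(7200, 7500))
})

test_that("GTF round trip converts 1-based coordinates and keeps structure", {
  m <- demo_models()
  gtf <- tempfile(fileext = ".gtf")
  write_models_gtf(m, gtf)
  # the GTF on disk is 1-based inclusive
  raw <- read.table(gtf, sep = "\t")
  expect_true(any(raw$V4 == 1001 & raw$V5 == 1200))
  m2 <- load_models(gtf)
  expect_equal(dplyr::arrange(m2$exons, tx_id, start),
               dplyr::arrange(m$exons, tx_id, start))
  expect_equal(dplyr::arrange(m2$transcripts, tx_id),
               dplyr::arrange(m$transcripts, tx_id))
})

test_that("hierarchical annotation picks the highest-priority category", {
  m <- demo_models()
  cases <- dplyr::bind_rows(
    tc_at(1000, id = "at_tss"),        # tx1 TSS, also inside tx2 exon
    tc_at(500, id = "alt_tss"),        # tx2 TSS
    tc_at(980, id = "upstream"),       # 20 bp upstream of tx1 TSS -> promoter radius
    tc_at(450, id = "proximal"),       # 50 bp upstream of tx2 TSS, outside radius?
    tc_at(1150, id = "cds"),           # tx1 CDS (but tx2 exon): CDS wins over exon
    tc_at(2300, id = "utr3"),          # tx1 3'UTR
    tc_at(1500, id = "intron"),        # tx1 intron, tx2 exon -> exon outranks intron
    tc_at(6500, "+", id = "antisense"),# inside geneB (-) only, wrong strand
    tc_at(6500, "-", id = "intronB"),  # geneB intron
    tc_at(9000, id = "intergenic")
  )
  ann <- annotate_clusters(cases, m)
  got <- setNames(as.character(ann$category), ann$feature_id)
  expect_equal(got[["at_tss"]], "promoter")
  expect_equal(got[["alt_tss"]], "promoter")
  expect_equal(got[["upstream"]], "promoter")
  expect_equal(got[["proximal"]], "promoter")  # within +/-100 bp radius
  expect_equal(got[["cds"]], "CDS")
  expect_equal(got[["utr3"]], "threeUTR")
  expect_equal(got[["intron"]], "exon")
  expect_equal(got[["antisense"]], "antisense")
  expect_equal(got[["intronB"]], "intron")
  expect_equal(got[["intergenic"]], "intergenic")
  # 500 bp upstream with no other overlap -> proximal
  prox <- annotate_clusters(tc_at(7999, "-", id = "p"), m)
  expect_equal(as.character(prox$category), "proximal")
  # annotation is total: every cluster gets exactly one category
  expect_false(anyNA(ann$category))
})

test_that("permuting category priority only moves multi-category clusters", {
  m <- demo_models()
  cases <- dplyr::bind_rows(tc_at(1150, id = "cds_exon"),
                            tc_at(9000, id = "lonely"))
  default <- annotate_clusters(cases, m)
  flipped <- annotate_clusters(
    cases, m,
    categories = c("promoter", "proximal", "fiveUTR", "threeUTR", "exon",
                   "CDS", "intron", "antisense", "intergenic"))
  expect_equal(as.character(default$category), c("CDS", "intergenic"))
  expect_equal(as.character(flipped$category), c("exon", "intergenic"))
})

test_that("enhancer candidates exclude exonic and promoter-proximal BCs", {
  m <- demo_models()
  bc_at <- function(mid, id) {
    tibble::tibble(feature_id = id, chrom = "chr1", start = mid - 200,
                   end = mid + 201, strand = ".", midpoint = mid,
                   balance = 1, score = 1)
  }
  bcs <- dplyr::bind_rows(
    bc_at(6650, "intronic"),    # inside geneB intron, span clear of exons
    bc_at(1500, "exonic"),      # span overlaps tx2 exon
    bc_at(7800, "near_tss"),    # 300 bp upstream of geneB TSS (7499)
    bc_at(9500, "intergenic")
  )
  kept <- select_enhancer_candidates(bcs, m)
  expect_equal(sort(kept$feature_id), c("intergenic", "intronic"))
  expect_equal(as.character(kept$category[kept$feature_id == "intronic"]),
               "intron")
})

test_that("gene assignment uses extended spans and nearest TSS for overlaps", {
  m <- demo_models()
  asg <- assign_genes(dplyr::bind_rows(
    tc_at(1500, id = "inA"),
    tc_at(4000, id = "between"),
    tc_at(6200, "-", id = "inB"),
    tc_at(8200, "-", id = "upB"),    # 700 bp upstream of geneB -> extended span
    tc_at(6200, "+", id = "wrong_strand")
  ), m)
  got <- setNames(asg$gene_id, asg$feature_id)
  expect_equal(unname(got[c("inA", "inB", "upB")]),
               c("geneA", "geneB", "geneB"))
  expect_true(is.na(got[["between"]]))
  expect_true(is.na(got[["wrong_strand"]]))
  # nested genes resolve by nearest TSS
  nest <- tx_models(tibble::tibble(
    chrom = "chr1", start = c(100, 300), end = c(2000, 700),
    strand = "+", tx_id = c("o", "i"), gene_id = c("outer", "inner")
  ))
  near <- assign_genes(tc_at(400, id = "x"), nest)
  expect_equal(near$gene_id, "inner")
})

test_that("gene matrix sums assigned TCs and conserves their counts", {
  ds <- make_dataset(list(
    s1 = list(`+` = c(`1000` = 10, `1500` = 5, `9000` = 3)),
    s2 = list(`+` = c(`1000` = 2))
  ))
  tcs <- dplyr::bind_rows(tc_at(1000, id = "a"), tc_at(1500, id = "b"),
                          tc_at(9000, id = "c"))
  em <- quantify_ranges(ds, tcs, "same-strand")
  asg <- tibble::tibble(feature_id = c("a", "b", "c"),
                        gene_id = c("g1", "g1", NA))
  gm <- gene_matrix(em, asg)
  expect_equal(unname(expr_counts(gm)["g1", ]), c(15, 2))
  expect_equal(sum(expr_counts(gm)),
               sum(expr_counts(em)[c("a", "b"), ]))
})

test_that("composition filter keeps majority TCs and all unassigned TCs", {
  counts <- rbind(a = c(95, 90, 90), b = c(5, 10, 10), c = c(30, 40, 50))
  em <- structure(
    dplyr::bind_cols(tibble::tibble(feature_id = c("a", "b", "c")),
                     tibble::as_tibble(`colnames<-`(counts, c("s1", "s2", "s3")))),
    samples = c("s1", "s2", "s3"), class = c("ctss_expr", class(tibble::tibble()))
  )
  asg <- tibble::tibble(feature_id = c("a", "b", "c"),
                        gene_id = c("g1", "g1", NA))
  cf <- composition_filter(em, asg, min_fraction = 0.1, min_samples = 0)
  expect_equal(cf$keep, c(TRUE, FALSE, TRUE))  # b never strictly exceeds 10%
  cf2 <- composition_filter(em, asg, min_fraction = 0.1, min_samples = 1)
  expect_equal(cf2$keep[cf2$feature_id == "b"], FALSE)
  # single-TC gene has fraction 1 everywhere
  asg3 <- tibble::tibble(feature_id = c("a", "b", "c"),
                         gene_id = c("g1", "g2", NA))
  expect_true(all(composition_filter(em, asg3)$keep))
  # zero gene totals count as failing samples
  z <- em; for (s in c("s1", "s2", "s3")) z[[s]] <- c(0, 0, 1)
  cfz <- composition_filter(z, asg, 0.1, 0)
  expect_false(any(cfz$keep[1:2]))
})

test_that("multi-TC summary counts genes before and after filtering", {
  asg <- tibble::tibble(
    feature_id = sprintf("t%d", 1:7),
    gene_id = c("g1", "g2", "g2", "g3", "g3", "g3", "g4")
  )
  s <- multi_tc_summary(asg, kept_ids = c("t1", "t2", "t4", "t5", "t7"))
  expect_equal(s$n_total, c(1, 2, 3, 1))
  expect_equal(s$n_kept, c(1, 1, 2, 1))
  f <- multi_tc_fraction(s)
  expect_equal(f$frac_multi_total, 0.5)
  expect_equal(f$frac_multi_kept, 0.25)
  # filtering can only lower the multi-TC fraction
  expect_lte(f$frac_multi_kept, f$frac_multi_total)
})
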