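test_that("library sizes sum raw tags over both strands per sample", {
  ds <- make_dataset(list(
    s1 = list(`+` = c(`10` = 5, `20` = 3), `-` = c(`15` = 2)),
    s2 = list(`+` = c(`10` = 10))
  ))
  expect_equal(unname(library_sizes(ds)), c(10, 10))
})

test_that("TPM normalization matches its definition and conserves 1e6", {
  ds <- make_dataset(list(
    s1 = list(`+` = c(`10` = 4, `50` = 1999996)),
    s2 = list(`+` = c(`10` = 1, `60` = 9))
  ))
  ds <- normalize_tpm(ds)
  expect_equal(ds$ctss$tpm[ds$ctss$sample == "s1" & ds$ctss$pos == 10], 2.0)
  sums <- tapply(ds$ctss$tpm, ds$ctss$sample, sum)
  expect_equal(as.numeric(sums), c(1e6, 1e6), tolerance = 1e-9)
  # same counts, different library sizes -> different TPM
  expect_false(ds$ctss$tpm[ds$ctss$sample == "s1" & ds$ctss$pos == 10] ==
                 ds$ctss$tpm[ds$ctss$sample == "s2" & ds$ctss$pos == 60] / 9)
})

test_that("zero-size library errors on normalization", {
  expect_warning(
    ds <- ctss_dataset(
      tibble::tibble(chrom = "chr1", pos = 1, strand = "+", sample = "s1",
                     count = 1),
      tiny_genome(), samples = c("s1", "s2")),
    "zero tags")
  expect_error(normalize_tpm(ds), "zero-size")
})

test_that("support filter keeps a bp iff enough samples reach the count", {
  ds <- make_dataset(list(
    s1 = list(`+` = c(`100` = 5, `200` = 1)),
    s2 = list(`+` = c(`200` = 1)),
    s3 = list(`+` = c(`300` = 2))
  ))
  f <- support_filter_ctss(ds, min_samples = 2, min_count = 1)
  # bp 100 and 300 seen in one sample each -> removed everywhere
  expect_equal(sort(unique(f$ctss$pos)), 200)
  # counts (0,1,1) across samples with k=2,c=1 -> kept
  expect_equal(nrow(f$ctss), 2)
  # identity at k=1,c=1 and idempotence
  expect_equal(support_filter_ctss(ds, 1, 1)$ctss, ds$ctss)
  expect_equal(support_filter_ctss(f, 2, 1)$ctss, f$ctss)
})

test_that("pooling sums per-sample TPM and conserves n_samples x 1e6", {
  ds <- normalize_tpm(make_dataset(list(
    s1 = list(`+` = c(`10` = 1, `20` = 3)),
    s2 = list(`+` = c(`10` = 2), `-` = c(`30` = 2))
  )))
  pooled <- pool_ctss(ds)
  expect_equal(sum(pooled$score), 2 * 1e6, tolerance = 1e-9)
  v10 <- pooled$score[pooled$pos == 10]
  expect_equal(v10, 1e6 / 4 + 2e6 / 4)  # sum, not mean
  expect_equal(pooled$score[pooled$pos == 30], 1e6 / 2)
})

test_that("quantify_ranges sums counts by strand mode and is additive", {
  ds <- make_dataset(list(
    s1 = list(`+` = c(`10` = 10, `12` = 3, `50` = 4), `-` = c(`10` = 10))
  ))
  r <- tibble::tibble(feature_id = c("a", "b"), chrom = "chr1",
                      start = c(9, 40), end = c(13, 60),
                      strand = c("+", "+"))
  em <- quantify_ranges(ds, r, "same-strand")
  expect_equal(unname(expr_counts(em)[, 1]), c(13, 4))
  # both-strands over a divergent pair
  rb <- tibble::tibble(feature_id = "bc", chrom = "chr1", start = 9, end = 11,
                       strand = ".")
  expect_equal(unname(expr_counts(quantify_ranges(ds, rb, "both-strands"))[, 1]),
               20)
  expect_error(quantify_ranges(ds, rb, "same-strand"), "stranded")
  # splitting a range sums to the whole
  rs <- tibble::tibble(feature_id = c("a1", "a2"), chrom = "chr1",
                       start = c(9, 11), end = c(11, 13), strand = "+")
  expect_equal(sum(expr_counts(quantify_ranges(ds, rs, "same-strand"))),
               unname(expr_counts(em)["a", 1]))
})

test_that("disjoint ranges partitioning all entries recover library sizes", {
  ds <- make_dataset(list(
    s1 = list(`+` = c(`10` = 5), `-` = c(`700` = 2)),
    s2 = list(`+` = c(`600` = 7))
  ))
  r <- tibble::tibble(feature_id = c("p1", "p2", "m1"), chrom = "chr1",
                      start = c(0, 500, 0), end = c(500, 1000, 1000),
                      strand = c("+", "+", "-"))
  em <- quantify_ranges(ds, r, "same-strand")
  expect_equal(colSums(expr_counts(em)), library_sizes(ds))
})

test_that("feature_support applies strict/inclusive thresholds on the right layer", {
  ds <- make_dataset(list(
    s1 = list(`+` = c(`10` = 12)), s2 = list(`+` = c(`10` = 8)),
    s3 = list(`+` = c(`10` = 15))
  ))
  # force library sizes of 1e7 so TPM = count / 10
  ds$library_sizes[] <- 1e7
  em <- quantify_ranges(
    ds, tibble::tibble(feature_id = "f", chrom = "chr1", start = 0, end = 100,
                       strand = "+"), "same-strand")
  # TPM (1.2, 0.8, 1.5): > 1 TPM in at least two samples -> pass
  expect_true(unname(feature_support(em, 1, 2, use_tpm = TRUE)))
  expect_false(unname(feature_support(em, 1, 3, use_tpm = TRUE)))
  # counts (1,0,0,0,0,0,1): >= 1 in >= 7 samples -> fail (2 supporting)
  m7 <- make_dataset(c(
    list(a = list(`+` = c(`5` = 1))),
    setNames(rep(list(list(`+` = c(`9` = 1))), 5), paste0("b", 1:5)),
    list(c = list(`+` = c(`5` = 1)))
  ))
  em7 <- quantify_ranges(
    m7, tibble::tibble(feature_id = "f", chrom = "chr1", start = 5, end = 6,
                       strand = "+"), "same-strand")
  expect_false(unname(feature_support(em7, 1, 7, strict = FALSE)))
  expect_true(unname(feature_support(em7, 1, 2, strict = FALSE)))
  # all zeros fail any positive threshold
  z <- em7; for (s in expr_samples(z)) z[[s]] <- 0
  expect_false(unname(feature_support(z, 1, 1, strict = FALSE)))
})

test_that("expression tables expose counts and a consistent TPM layer", {
  ds <- make_dataset(list(s1 = list(`+` = c(`10` = 5)),
                          s2 = list(`+` = c(`10` = 20))))
  em <- quantify_ranges(
    ds, tibble::tibble(feature_id = "f", chrom = "chr1", start = 0, end = 20,
                       strand = "+"), "same-strand")
  expect_equal(expr_samples(em), c("s1", "s2"))
  tpm <- expr_counts(expr_tpm(em))
  expect_equal(unname(tpm[1, ]), c(5 * 1e6 / 5, 20 * 1e6 / 20))
})
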