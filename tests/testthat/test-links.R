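tc_row <- function(id, peak, chrom = "chr1") {
  tibble::tibble(feature_id = id, chrom = chrom, start = peak - 10,
                 end = peak + 10, strand = "+", peak = peak)
}

enh_row <- function(id, mid, chrom = "chr1") {
  tibble::tibble(feature_id = id, chrom = chrom, start = mid - 200,
                 end = mid + 200, strand = ".", midpoint = mid)
}

test_that("candidate pairs respect the distance window per chromosome", {
  tcs <- dplyr::bind_rows(tc_row("t1", 1000), tc_row("t2", 3000),
                          tc_row("t3", 8000), tc_row("t4", 1000, "chr2"))
  enh <- dplyr::bind_rows(enh_row("e1", 5000), enh_row("e2", 16000))
  p <- candidate_pairs(tcs, enh, max_dist = 10000)
  # e1 pairs with all three chr1 TCs; e2 (15 kbp from t1) only with t3
  expect_equal(nrow(p), 4)
  expect_equal(sort(p$tc_id[p$enhancer_id == "e1"]), c("t1", "t2", "t3"))
  expect_equal(p$tc_id[p$enhancer_id == "e2"], "t3")
  expect_equal(p$distance[p$tc_id == "t1" & p$enhancer_id == "e1"], 4000)
  # 3 TCs x 2 enhancers all within the window -> full cross product
  close <- dplyr::bind_rows(enh_row("e1", 5000), enh_row("e2", 6000))
  expect_equal(nrow(candidate_pairs(tcs[1:3, ], close, 10000)), 6)
})

test_that("Kendall links match closed-form taus and the pair-count oracle", {
  pairs <- tibble::tibble(tc_id = c("t1", "t2", "t3"),
                          enhancer_id = c("e1", "e1", "e1"),
                          chrom = "chr1", distance = 1000)
  tcm <- rbind(t1 = c(1, 2, 3, 4), t2 = c(4, 3, 2, 1), t3 = c(1, 3, 2, 4))
  enm <- rbind(e1 = c(1, 2, 3, 4))
  links <- correlate_links(pairs, mk_expr(tcm), mk_expr(enm))
  expect_equal(links$estimate, c(1, -1, 2 / 3))
  expect_equal(links$p_adj, bh_adjust(links$p_value))
  set.seed(9)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- sample(0:3, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    got <- correlate_links(
      tibble::tibble(tc_id = "t", enhancer_id = "e", chrom = "c", distance = 0),
      mk_expr(rbind(t = x)), mk_expr(rbind(e = y)))
    expect_equal(got$estimate, oracle_tau_b(x, y), tolerance = 1e-12)
  }
})

test_that("constant profiles are dropped with a warning, order mismatch errors", {
  pairs <- tibble::tibble(tc_id = c("t1", "t2"), enhancer_id = "e1",
                          chrom = "chr1", distance = 0)
  tcm <- rbind(t1 = c(5, 5, 5, 5), t2 = c(1, 2, 3, 4))
  enm <- rbind(e1 = c(2, 1, 4, 3))
  expect_warning(links <- correlate_links(pairs, mk_expr(tcm), mk_expr(enm)),
                 "constant")
  expect_equal(links$tc_id, "t2")
  expect_error(
    correlate_links(pairs, mk_expr(tcm),
                    mk_expr(enm, samples = c("s2", "s1", "s3", "s4"))),
    "sample order")
})

test_that("custom correlation functions are accepted", {
  pairs <- tibble::tibble(tc_id = "t", enhancer_id = "e", chrom = "c",
                          distance = 0)
  got <- correlate_links(pairs, mk_expr(rbind(t = c(1, 2, 3))),
                         mk_expr(rbind(e = c(3, 2, 1))),
                         method = function(x, y) list(estimate = -0.5,
                                                      p.value = 0.2))
  expect_equal(got$estimate, -0.5)
  expect_equal(got$p_value, 0.2)
})

test_that("BH adjustment matches the hand step-up and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- stats::runif(30)
  o <- sample(30)
  # order invariance and monotonicity
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("stretches chain enhancers by edge-to-edge gaps below 12.5 kbp", {
  enh <- dplyr::bind_rows(
    enh_row("e1", 500), enh_row("e2", 10500), enh_row("e3", 30500)
  )
  # spans are mid +/- 200: gaps are 9.6 kbp and 19.6 kbp
  st <- find_stretches(enh, merge_dist = 12500, min_members = 2)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_members, 2)
  expect_equal(st$members[[1]], c("e1", "e2"))
  expect_equal(c(st$start, st$end), c(300, 10700))
  # all gaps at or above the threshold -> no stretches
  expect_equal(nrow(find_stretches(enh, merge_dist = 9000, min_members = 2)), 0)
  # five enhancers 1 kbp apart form a single stretch
  run <- dplyr::bind_rows(lapply(1:5, function(i) enh_row(paste0("r", i),
                                                          i * 1000)))
  st5 <- find_stretches(run, 12500, 4)
  expect_equal(st5$n_members, 5)
  # the gap rule is strictly less-than
  touching <- dplyr::bind_rows(enh_row("a", 1000), enh_row("b", 1000 + 12900))
  # gap = 12900 - 400 = 12500 exactly -> not merged
  expect_equal(nrow(find_stretches(touching, 12500, 2)), 0)
})

test_that("stretch correlations average all member pairs", {
  m <- rbind(e1 = c(1, 2, 3, 4), e2 = c(1, 2, 3, 4), e3 = c(4, 3, 2, 1))
  st <- tibble::tibble(stretch_id = c("s1", "s2"), chrom = "chr1",
                       start = 0, end = 1,
                       n_members = c(3, 1),
                       members = list(c("e1", "e2", "e3"), "e1"))
  got <- stretch_correlations(st, mk_expr(m))
  # pairwise taus: (e1,e2)=1, (e1,e3)=-1, (e2,e3)=-1 -> mean -1/3
  expect_equal(got$avg_cor, c(-1 / 3, NA))
  ident <- tibble::tibble(stretch_id = "s", chrom = "c", start = 0, end = 1,
                          n_members = 2, members = list(c("e1", "e2")))
  expect_equal(stretch_correlations(ident, mk_expr(m))$avg_cor, 1)
  anti <- tibble::tibble(stretch_id = "s", chrom = "c", start = 0, end = 1,
                         n_members = 2, members = list(c("e1", "e3")))
  expect_equal(stretch_correlations(anti, mk_expr(m))$avg_cor, -1)
})
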