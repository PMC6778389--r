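#' Configuration for the synthetic CTSS data generator
#'
#' Describes a multi-sample CTSS experiment with planted unidirectional tag
#' clusters (sharp and broad), planted divergent (enhancer-like) loci,
#' transcript models wrapping the planted TCs, background noise and,
#' optionally, TC-enhancer pairs sharing a latent activity. Defaults describe
#' a small but realistic experiment: 5 libraries, 50 TCs (half sharp, half
#' broad) and 20 enhancers at a mean of 50 tags per feature and sample with
#' negative-binomial overdispersion 0.2, and sparse Poisson background noise
#' of 1e-5 tags per bp per strand per sample.
#'
#' @param seed Integer seed; the whole simulation is reproducible given it.
#' @param n_samples Number of libraries.
#' @param chrom,chrom_length Synthetic chromosome name and length (bp).
#' @param n_sharp,n_broad Number of planted sharp/broad tag clusters. Sharp
#'   TCs place >= 90% of their tags within 2 bp of the peak; broad TCs mix a
#'   dominant summit with tags spread over a 40-100 bp region.
#' @param n_enhancers Planted divergent loci: minus-strand tags upstream and
#'   plus-strand tags downstream of the midpoint, arm offsets 10-180 bp,
#'   plus/minus totals split binomially around 50/50.
#' @param mean_expression Mean tags per feature per sample.
#' @param dispersion Negative-binomial overdispersion (variance = mu +
#'   dispersion * mu^2); biological replicates are overdispersed relative to
#'   Poisson.
#' @param noise_rate Expected background tags per bp per strand per sample
#'   (independent single-tag CTSSs).
#' @param n_links Number of TC-enhancer pairs sharing a latent activity;
#'   such pairs are placed within one slot spacing (well inside the 10 kbp
#'   pairing window).
#' @param link_rho Correlation of the paired features' latent log-activities.
#' @param activity_sd Standard deviation of the latent log-normal activity
#'   every feature fluctuates with across samples.
#' @param spacing Distance between feature slots (bp); features are jittered
#'   within their slot.
#' @param tcs_per_gene Number of consecutive same-strand TCs grouped into one
#'   gene in the generated transcript models.
#' @param tx_length Length of each generated transcript (bp downstream of its
#'   TC peak).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_samples = 5, chrom = "chrS",
                       chrom_length = 2e6, n_sharp = 25, n_broad = 25,
                       n_enhancers = 20, mean_expression = 50,
                       dispersion = 0.2, noise_rate = 1e-5, n_links = 0,
                       link_rho = 0.8, activity_sd = 1, spacing = 4000,
                       tcs_per_gene = 1, tx_length = 1500) {
  cfg <- as.list(environment())
  .assert(cfg$n_samples >= 1 && cfg$chrom_length > 0, "invalid config")
  .assert(cfg$mean_expression > 0, "expression must be > 0")
  .assert(cfg$n_links <= min(cfg$n_sharp + cfg$n_broad, cfg$n_enhancers),
          "n_links exceeds available TCs or enhancers")
  n_feat <- cfg$n_sharp + cfg$n_broad + cfg$n_enhancers
  .assert((n_feat + 2) * cfg$spacing < cfg$chrom_length,
          "infeasible placement: chromosome too short for the planted features")
  structure(cfg, class = "sim_config")
}

.sim_offsets_sharp <- function(n) {
  sample(-2:2, n, replace = TRUE, prob = c(0.05, 0.15, 0.6, 0.15, 0.05))
}

.sim_offsets_broad <- function(n, width) {
  summit <- stats::runif(n) < 0.3
  half <- floor(width / 2)
  off <- round(stats::rnorm(n, 0, width / 4))
  off <- pmax(-half, pmin(half, off))
  as.integer(ifelse(summit, 0L, off))
}

#' Simulate a multi-sample CTSS dataset with ground truth
#'
#' Generates sparse per-bp stranded CTSS counts for every sample, transcript
#' models wrapping the planted TCs, and a truth table recording each planted
#' feature's interval, anchor position, class and linked partner. Per-sample
#' tag totals are negative-binomial around the mean expression, modulated by
#' a per-feature log-normal activity across samples; features in a linked
#' pair share a correlated latent activity (correlation `link_rho`).
#' Background noise is a sparse field of single-tag CTSSs.
#'
#' @param config A [sim_config()].
#' @return List of class `ctss_sim` with elements `dataset` (a
#'   [ctss_dataset()]), `models` (a [tx_models()]), `truth` (tibble:
#'   `true_id`, `type`, `chrom`, `start`, `end`, `strand`, `anchor`,
#'   `shape_class`, `gene_id`, `partner_id`) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  set.seed(config$seed)
  n_tc <- config$n_sharp + config$n_broad
  n_feat <- n_tc + config$n_enhancers
  samples <- sprintf("S%02d", seq_len(config$n_samples))

  # --- placement: one jittered slot per feature; linked pairs adjacent -----
  slots <- seq(config$spacing, by = config$spacing, length.out = n_feat)
  feat <- tibble(
    true_id = c(sprintf("tc_%02d", seq_len(n_tc)),
                sprintf("enh_%02d", seq_len(config$n_enhancers))),
    type = rep(c("tc", "enhancer"), c(n_tc, config$n_enhancers)),
    shape_class = c(rep(c("sharp", "broad"), c(config$n_sharp, config$n_broad)),
                    rep(NA_character_, config$n_enhancers))
  )
  slot_of <- integer(n_feat)
  nl <- config$n_links
  if (nl > 0) {
    slot_of[seq_len(nl)] <- 2 * seq_len(nl) - 1             # linked TCs
    slot_of[n_tc + seq_len(nl)] <- 2 * seq_len(nl)          # their enhancers
    rest <- setdiff(seq_len(n_feat), c(seq_len(nl), n_tc + seq_len(nl)))
    slot_of[rest] <- sample(setdiff(seq_len(n_feat), slot_of[slot_of > 0]))
  } else {
    slot_of <- sample(n_feat)
  }
  feat$anchor <- slots[slot_of] + sample(-500:500, n_feat, replace = TRUE)
  feat$strand <- ifelse(feat$type == "tc",
                        sample(c("+", "-"), n_feat, replace = TRUE), ".")
  feat$partner_id <- NA_character_
  if (nl > 0) {
    feat$partner_id[seq_len(nl)] <- feat$true_id[n_tc + seq_len(nl)]
    feat$partner_id[n_tc + seq_len(nl)] <- feat$true_id[seq_len(nl)]
  }
  broad_width <- ifelse(feat$shape_class %in% "broad",
                        sample(40:100, n_feat, replace = TRUE), NA)

  # --- latent activities -----------------------------------------------------
  sd <- config$activity_sd
  rho <- config$link_rho
  act <- matrix(stats::rnorm(n_feat * config$n_samples), n_feat)
  if (nl > 0) {
    shared <- matrix(stats::rnorm(nl * config$n_samples), nl)
    act[seq_len(nl), ] <- sqrt(rho) * shared +
      sqrt(1 - rho) * act[seq_len(nl), ]
    act[n_tc + seq_len(nl), ] <- sqrt(rho) * shared +
      sqrt(1 - rho) * act[n_tc + seq_len(nl), ]
  }
  mu <- config$mean_expression * exp(sd * act - sd^2 / 2)

  # --- tag generation --------------------------------------------------------
  tags <- vector("list", n_feat * config$n_samples)
  k <- 0
  size <- 1 / config$dispersion
  for (i in seq_len(n_feat)) {
    for (s in seq_len(config$n_samples)) {
      n_tags <- stats::rnbinom(1, mu = mu[i, s], size = size)
      if (n_tags == 0) next
      k <- k + 1
      if (feat$type[i] == "tc") {
        off <- if (feat$shape_class[i] == "sharp") .sim_offsets_sharp(n_tags)
               else .sim_offsets_broad(n_tags, broad_width[i])
        tags[[k]] <- tibble(pos = feat$anchor[i] + off,
                            strand = feat$strand[i], sample = samples[s])
      } else {
        n_plus <- stats::rbinom(1, n_tags, 0.5)
        d <- sample(10:180, n_tags, replace = TRUE)
        pos <- c(feat$anchor[i] + d[seq_len(n_plus)],
                 feat$anchor[i] - d[seq_len(n_tags - n_plus) + n_plus])
        tags[[k]] <- tibble(pos = pos,
                            strand = rep(c("+", "-"),
                                         c(n_plus, n_tags - n_plus)),
                            sample = samples[s])
      }
    }
  }
  # background noise: independent single tags
  for (s in seq_len(config$n_samples)) {
    for (st in c("+", "-")) {
      n_noise <- stats::rpois(1, config$chrom_length * config$noise_rate)
      if (n_noise == 0) next
      k <- k + 1
      tags[[k]] <- tibble(pos = sample.int(config$chrom_length, n_noise) - 1,
                          strand = st, sample = samples[s])
    }
  }
  ctss <- dplyr::bind_rows(tags[seq_len(k)]) %>%
    dplyr::count(.data$pos, .data$strand, .data$sample, name = "count") %>%
    dplyr::mutate(chrom = config$chrom, .before = 1) %>%
    dplyr::filter(.data$pos >= 0 & .data$pos < config$chrom_length)

  gen <- tibble(chrom = config$chrom, length = config$chrom_length)
  dataset <- ctss_dataset(ctss, gen, samples = samples)

  # --- truth intervals -------------------------------------------------------
  half <- ifelse(feat$type == "enhancer", 181,
                 ifelse(feat$shape_class == "sharp", 3,
                        floor(broad_width / 2) + 1))
  truth <- feat %>%
    dplyr::mutate(
      chrom = config$chrom,
      start = pmax(0, .data$anchor - half),
      end = pmin(config$chrom_length, .data$anchor + half)
    )

  # --- transcript models wrapping the TCs ------------------------------------
  models <- .sim_models(truth[truth$type == "tc", ], config)
  truth <- dplyr::left_join(
    truth,
    dplyr::select(models$tx_of, "true_id", "gene_id"),
    by = "true_id"
  )
  truth <- truth[, c("true_id", "type", "chrom", "start", "end", "strand",
                     "anchor", "shape_class", "gene_id", "partner_id")]
  structure(
    list(dataset = dataset, models = models$models, truth = truth,
         config = config),
    class = "ctss_sim"
  )
}

# Transcripts: one per TC, TSS at the TC peak, two exons and a CDS so all
# annotation categories are exercised; consecutive same-strand TCs grouped
# into genes of size tcs_per_gene.
.sim_models <- function(tc_truth, config) {
  tc_truth <- dplyr::arrange(tc_truth, .data$strand, .data$anchor)
  n <- nrow(tc_truth)
  grp <- stats::ave(seq_len(n), tc_truth$strand,
                    FUN = function(ix) ceiling(seq_along(ix) / config$tcs_per_gene))
  grp <- paste0(tc_truth$strand, grp)
  gene_ids <- sprintf("gene_%02d", match(grp, unique(grp)))
  L <- config$tx_length
  p <- tc_truth$anchor
  plus <- tc_truth$strand == "+"
  ex <- dplyr::bind_rows(
    tibble(start = ifelse(plus, p, p - 200 + 1),
           end = ifelse(plus, p + 200, p + 1), n_ex = 1),
    tibble(start = ifelse(plus, p + 800, p - L + 1),
           end = ifelse(plus, p + L, p - 800 + 1), n_ex = 2)
  )
  idx <- rep(seq_len(n), 2)
  exons <- tibble(
    chrom = config$chrom,
    start = ex$start, end = ex$end,
    strand = tc_truth$strand[idx],
    tx_id = paste0("tx_", tc_truth$true_id[idx]),
    gene_id = gene_ids[idx]
  )
  cds_s <- ifelse(plus, p + 100, p - 1200 + 1)
  cds_e <- ifelse(plus, p + 1200, p - 100 + 1)
  # clip CDS pieces to the exons they fall in
  cds <- dplyr::bind_rows(
    dplyr::mutate(exons[idx <= n, ], start = pmax(.data$start, cds_s),
                  end = pmin(.data$end, cds_e)),
    dplyr::mutate(exons[idx > n, ], start = pmax(.data$start, cds_s),
                  end = pmin(.data$end, cds_e))
  )
  cds <- dplyr::filter(cds, .data$end > .data$start)
  list(
    models = tx_models(exons, cds),
    tx_of = tibble(true_id = tc_truth$true_id, gene_id = gene_ids)
  )
}

#' @export
print.ctss_sim <- function(x, ...) {
  cat("Synthetic CTSS experiment:", length(x$dataset$samples), "samples;",
      sum(x$truth$type == "tc"), "planted TCs,",
      sum(x$truth$type == "enhancer"), "planted enhancers\n")
  invisible(x)
}

#' Match called features to planted truth
#'
#' A called feature matches a planted one when their intervals overlap and
#' the called anchor (TC peak / BC midpoint) lies within `max_dist` of the
#' true anchor.
#'
#' @param called Cluster tibble (TCs or BCs).
#' @param truth Truth tibble from [simulate_dataset()].
#' @param type `"tc"` or `"enhancer"` (selects truth rows and the default
#'   tolerance).
#' @param max_dist Anchor tolerance in bp; defaults to 5 for TCs and 50 for
#'   enhancers (stricter than the default merge distances).
#' @return Tibble `feature_id`, `true_id`, `distance` (one row per matched
#'   pair).
#' @export
match_features <- function(called, truth, type = c("tc", "enhancer"),
                           max_dist = NULL) {
  type <- match.arg(type)
  if (is.null(max_dist)) max_dist <- if (type == "tc") 5 else 50
  tr <- truth[truth$type == type, , drop = FALSE]
  called <- as_tibble(called)
  if (nrow(called) == 0 || nrow(tr) == 0) {
    return(tibble(feature_id = character(), true_id = character(),
                  distance = numeric()))
  }
  anchor <- .cluster_anchor(called)
  grid <- dplyr::inner_join(
    tibble(feature_id = called$feature_id, chrom = called$chrom,
           s = called$start, e = called$end, a = anchor),
    tibble(true_id = tr$true_id, chrom = tr$chrom, ts = tr$start,
           te = tr$end, ta = tr$anchor),
    by = "chrom", relationship = "many-to-many"
  )
  grid %>%
    dplyr::filter(.data$s < .data$te, .data$ts < .data$e,
                  abs(.data$a - .data$ta) <= .env$max_dist) %>%
    dplyr::mutate(distance = abs(.data$a - .data$ta)) %>%
    dplyr::select("feature_id", "true_id", "distance")
}

#' Precision/recall of called features against planted truth
#'
#' @inheritParams match_features
#' @return One-row tibble: `type`, `n_true`, `n_called`, `n_matched`
#'   (distinct recovered truths), `precision` (fraction of called features
#'   matching some truth), `recall`, and `peak_distances` (list column with
#'   the matched anchor distances).
#' @export
evaluate_recovery <- function(called, truth, type = c("tc", "enhancer"),
                              max_dist = NULL) {
  type <- match.arg(type)
  tr <- truth[truth$type == type, , drop = FALSE]
  m <- match_features(called, truth, type, max_dist)
  n_called <- nrow(as_tibble(called))
  tibble(
    type = type,
    n_true = nrow(tr),
    n_called = n_called,
    n_matched = dplyr::n_distinct(m$true_id),
    precision = if (n_called == 0) NA_real_ else
      dplyr::n_distinct(m$feature_id) / n_called,
    recall = if (nrow(tr) == 0) NA_real_ else
      dplyr::n_distinct(m$true_id) / nrow(tr),
    peak_distances = list(m$distance)
  )
}
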