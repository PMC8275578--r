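fake_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%05d", 1:n),
             cpg_oe = runif(n, 0.2, 1.2), stringsAsFactors = FALSE)
}

test_that("quantile bins are equally sized with remainders in the lowest bins", {
  b100 <- quantile_bins(fake_records(100), 25)
  expect_equal(as.integer(table(b100$bin)), rep(4L, 25))
  b101 <- quantile_bins(fake_records(101), 25)
  sizes <- as.integer(table(b101$bin))
  expect_equal(sizes, c(5L, rep(4L, 24)))
  expect_true(all(diff(b101$cpg_oe) >= 0))
  expect_error(quantile_bins(fake_records(10), 25), "bins")
})

test_that("tied CpG values bin deterministically by gene id", {
  rec <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    cpg_oe = rep(0.5, 20))
  b1 <- quantile_bins(rec, 4)
  b2 <- quantile_bins(rec[sample(20), ], 4)
  m <- match(b1$gene_id, b2$gene_id)
  expect_identical(b1$bin, b2$bin[m])
})

test_that("per-bin DEG counts are conserved and the planted trend is found", {
  # planted: DE probability rises with cpg_oe via a logistic link
  set.seed(71)
  n <- 10000
  rec <- fake_records(n, seed = 71)
  p_de <- plogis(-4 + 3 * rec$cpg_oe)
  de <- data.frame(gene_id = rec$gene_id,
                   magnitude = rnorm(n, 0, 0.1),
                   is_deg = rbinom(n, 1, p_de) == 1)
  bins <- quantile_bins(rec, 25)
  bf <- bin_frequency(bins, de, threshold = 0.7)
  expect_equal(sum(bf$table$n_deg), sum(de$is_deg))
  expect_gt(bf$correlation$estimate, 0.5)
  expect_lt(bf$correlation$p_value, 0.01)
  expect_identical(bf$table$component,
                   ifelse(bf$table$mean_cpg_oe < 0.7, "low", "high"))

  # all DEGs concentrated in the top bin stay there
  de2 <- de
  top_ids <- bins$gene_id[bins$bin == 25]
  de2$is_deg <- de2$gene_id %in% top_ids[1:50]
  bf2 <- bin_frequency(bins, de2)
  expect_equal(bf2$table$n_deg[25], 50L)
  expect_equal(sum(bf2$table$n_deg[-25]), 0L)
})

test_that("a flat link yields no spurious frequency trend", {
  weak <- vapply(1:5, function(s) {
    set.seed(300 + s)
    n <- 5000
    rec <- fake_records(n, seed = 300 + s)
    de <- data.frame(gene_id = rec$gene_id, magnitude = 0,
                     is_deg = rbinom(n, 1, 0.08) == 1)
    bf <- bin_frequency(quantile_bins(rec, 25), de)
    abs(bf$correlation$estimate) < 0.3
  }, TRUE)
  expect_gte(sum(weak), 4)
})

test_that("magnitude bins track a planted monotone trend", {
  set.seed(72)
  n <- 6000
  rec <- fake_records(n, seed = 72)
  de <- data.frame(gene_id = rec$gene_id,
                   magnitude = 0.2 * rec$cpg_oe + rnorm(n, 0, 0.02),
                   is_deg = FALSE)
  bins <- quantile_bins(rec, 12)
  bm <- bin_magnitude(bins, de, threshold = 0.7)
  expect_equal(nrow(bm$table), 12L)
  expect_gt(bm$spearman$estimate, 0.95)
  expect_lt(bm$anova$p_value, 1e-6)

  # |magnitude| makes the analysis invariant to contrast direction
  de_neg <- de
  de_neg$magnitude <- -de$magnitude
  bm_neg <- bin_magnitude(bins, de_neg, threshold = 0.7)
  expect_equal(bm$table$mean_magnitude, bm_neg$table$mean_magnitude)

  # constant magnitudes: ANOVA flat, correlations flagged undefined
  de_flat <- de
  de_flat$magnitude <- 0.3
  bm_flat <- suppressMessages(bin_magnitude(bins, de_flat))
  expect_equal(bm_flat$anova$statistic, 0)
  expect_null(bm_flat$pearson)
})

test_that("component contrasts detect a planted rate difference", {
  set.seed(73)
  n <- 10000
  rec <- fake_records(n, seed = 73)
  split <- classify_genes(rec, 0.7)
  comp <- setNames(split$genes$component, split$genes$gene_id)
  p_de <- ifelse(comp[rec$gene_id] == "high", 0.16, 0.08)
  de <- data.frame(gene_id = rec$gene_id,
                   magnitude = rnorm(n, 0, 0.1) +
                     ifelse(comp[rec$gene_id] == "high", 0.05, 0),
                   is_deg = rbinom(n, 1, p_de) == 1)
  bf <- bin_frequency(quantile_bins(rec, 25), de, threshold = 0.7)
  cc <- component_contrast(bf$table, split, de)
  expect_lt(cc$frequency$p_value, 0.05)
  expect_lt(cc$magnitude$p_value, 0.05)
  expect_gt(cc$summary$mean_bin_deg[cc$summary$component == "high"],
            cc$summary$mean_bin_deg[cc$summary$component == "low"])

  # identical per-bin counts in both components cannot be significant
  tab <- bf$table
  tab$n_deg <- 10L
  cc_flat <- component_contrast(tab, split, de)
  expect_equal(cc_flat$frequency$p_value, 1)
})

test_that("population slope ratios behave linearly", {
  tab <- data.frame(bin = 1:25, n_genes = 40,
                    mean_cpg_oe = seq(0.3, 1.1, length.out = 25),
                    n_deg = round(seq(2, 40, length.out = 25)))
  expect_equal(population_slopes(tab, tab)$ratio, 1)
  tab3 <- tab
  tab3$n_deg <- tab$n_deg * 3L
  expect_equal(population_slopes(tab3, tab)$ratio, 3, tolerance = 1e-9)
  flat <- tab
  flat$n_deg <- 5L
  expect_true(is.na(suppressMessages(
    population_slopes(tab, flat))$ratio))
})

test_that("steeper links give steeper slopes across seeds", {
  hits <- vapply(1:5, function(s) {
    set.seed(500 + s)
    n <- 5000
    rec <- fake_records(n, seed = 500 + s)
    de_steep <- data.frame(gene_id = rec$gene_id, magnitude = 0,
                           is_deg = rbinom(n, 1,
                                           plogis(-4 + 3 * rec$cpg_oe)) == 1)
    de_shallow <- data.frame(gene_id = rec$gene_id, magnitude = 0,
                             is_deg = rbinom(n, 1,
                                             plogis(-2.9 + 1 * rec$cpg_oe)) == 1)
    bins <- quantile_bins(rec, 25)
    sl <- population_slopes(bin_frequency(bins, de_steep)$table,
                            bin_frequency(bins, de_shallow)$table)
    sl$ratio > 1
  }, TRUE)
  expect_gte(sum(hits), 4)
})
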