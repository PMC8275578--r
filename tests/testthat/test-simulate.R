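test_that("CpG targets follow the mixture with truncation and determinism", {
  cfg <- sim_config(n_genes = 50000L, seed = 81)
  set.seed(cfg$seed)
  tg <- simulate_cpg_targets(cfg)
  expect_lt(abs(mean(tg$true_component == "low") - 0.661), 0.01)
  expect_true(all(tg$target_oe >= 0.05 & tg$target_oe <= 2))

  set.seed(cfg$seed)
  tg2 <- simulate_cpg_targets(cfg)
  expect_identical(tg, tg2)

  # degenerate spread: all values collapse onto the component means
  cfg0 <- sim_config(n_genes = 500L,
                     mixture = list(lambda = c(0.5, 0.5),
                                    mu = c(0.4, 0.9),
                                    sigma = c(1e-6, 1e-6)))
  set.seed(1)
  tg0 <- simulate_cpg_targets(cfg0)
  expect_lt(max(abs(tg0$target_oe -
                      ifelse(tg0$true_component == "low", 0.4, 0.9))),
            1e-4)
})

test_that("simulated sequences realize their CpG targets", {
  cfg <- sim_config()
  # target 0 produces CG-free sequences
  set.seed(82)
  tg0 <- data.frame(gene_id = paste0("z", 1:50), target_oe = 0)
  s0 <- simulate_sequences(tg0, cfg, lengths = rep(500, 50))
  expect_equal(sum(count_dinucleotides(s0)$n_cpg), 0L)

  # neutral target: realized ratios centre on 1
  set.seed(83)
  tg1 <- data.frame(gene_id = paste0("n", 1:200), target_oe = 1)
  s1 <- simulate_sequences(tg1, cfg, lengths = rep(2000, 200))
  pr1 <- suppressMessages(profile_transcriptome(s1))
  expect_gt(mean(pr1$cpg_oe), 0.95)
  expect_lt(mean(pr1$cpg_oe), 1.05)

  # calibration: realized ratio regresses on target with slope near 1
  set.seed(84)
  tg <- data.frame(gene_id = sprintf("c%03d", 1:300),
                   target_oe = seq(0.3, 1.2, length.out = 300))
  ss <- simulate_sequences(tg, cfg, lengths = rep(2000, 300))
  pr <- suppressMessages(profile_transcriptome(ss))
  slope <- linear_fit(tg$target_oe, pr$cpg_oe)$slope
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)

  expect_error(simulate_sequences(
    data.frame(gene_id = "g", target_oe = 1 / cfg$gc * 2 + 0.1),
    cfg), "infeasible")
})

test_that("annotation bias is absent at 1 and reproducible under a seed", {
  cfg <- sim_config(n_genes = 2000L)
  set.seed(85)
  tg <- simulate_cpg_targets(cfg)

  indep <- vapply(1:5, function(s) {
    set.seed(600 + s)
    ann <- simulate_annotations(tg, bias = 1)
    pools <- slim_term_pools()
    is_const <- ann$term %in% pools$constitutive
    comp <- setNames(tg$true_component, tg$gene_id)[ann$gene_id]
    suppressWarnings(chisq.test(table(is_const, comp))$p.value) > 0.05
  }, TRUE)
  expect_gte(sum(indep), 4)

  set.seed(86)
  a1 <- simulate_annotations(tg, bias = 3)
  set.seed(86)
  a2 <- simulate_annotations(tg, bias = 3)
  expect_identical(a1, a2)
  expect_true(all(tg$gene_id %in% a1$gene_id))  # every gene annotated

  expect_error(simulate_annotations(
    tg, pools = list(constitutive = character(0), responsive = "x")),
    "non-empty")
})

test_that("biased annotations drive recoverable enrichment", {
  cfg <- sim_config(n_genes = 2000L)
  set.seed(87)
  tg <- simulate_cpg_targets(cfg)
  ann <- simulate_annotations(tg, bias = 3)
  rec <- data.frame(gene_id = tg$gene_id, cpg_oe = tg$target_oe)
  split <- classify_genes(rec, 0.67)
  enr <- fisher_enrichment(split, ann)
  pools <- slim_term_pools()
  sig <- enr[enr$significant, ]
  expect_gt(nrow(sig), 0)
  const_sig <- sig[sig$term %in% pools$constitutive, ]
  expect_true(all(const_sig$direction == "low-enriched"))
  expect_gt(nrow(const_sig), 0)
})

test_that("counts honour the link rate, the Poisson limit and the seed", {
  cfg <- sim_config(n_genes = 10000L, de_a = qlogis(0.1), de_b = 0)
  set.seed(88)
  tg <- simulate_cpg_targets(cfg)
  sim <- simulate_counts(tg, cfg)
  expect_lt(abs(mean(sim$truth$origin_responsive) - 0.1), 0.02)
  expect_equal(dim(sim$counts), c(10000L, 12L))
  expect_equal(sim$design$sample_id, colnames(sim$counts))

  # phi = 0: within-cell variance tracks the mean
  cfg0 <- sim_config(n_genes = 4000L, phi = 0, de_a = -50,
                     baseline_meanlog = log(200), baseline_sdlog = 0.3,
                     depth_range = c(1, 1))
  set.seed(89)
  tg0 <- simulate_cpg_targets(cfg0)
  sim0 <- simulate_counts(tg0, cfg0)
  cell <- sim0$counts[, sim0$design$origin == "cold" &
                        sim0$design$treatment == "control"]
  ratio <- apply(cell, 1, var) / rowMeans(cell)
  expect_lt(abs(mean(ratio) - 1), 0.05)

  set.seed(90)
  s1 <- simulate_counts(tg, cfg)
  set.seed(90)
  s2 <- simulate_counts(tg, cfg)
  expect_identical(s1$counts, s2$counts)
})

test_that("threshold classification approaches the Bayes accuracy", {
  cfg <- sim_config(n_genes = 50000L)
  set.seed(91)
  tg <- simulate_cpg_targets(cfg)
  thr <- component_intersection(
    mixture_params(cfg$mixture$lambda, cfg$mixture$mu, cfg$mixture$sigma))
  pred <- ifelse(tg$target_oe < thr, "low", "high")
  acc <- mean(pred == tg$true_component)
  # the intersection rule IS the Bayes rule for the mixture; estimate the
  # Bayes rate by the expected posterior of the chosen class
  d_low <- cfg$mixture$lambda[1] *
    dnorm(tg$target_oe, cfg$mixture$mu[1], cfg$mixture$sigma[1])
  d_high <- cfg$mixture$lambda[2] *
    dnorm(tg$target_oe, cfg$mixture$mu[2], cfg$mixture$sigma[2])
  bayes <- mean(pmax(d_low, d_high) / (d_low + d_high))
  expect_gt(acc, bayes - 0.05)
})

test_that("a written study round-trips through the readers", {
  dir <- tempfile("study")
  cfg <- sim_config(n_genes = 300L, seed = 92)
  study <- suppressMessages(simulate_study(cfg, dir = dir))
  seqs <- read_fasta(study$paths$fasta)
  expect_identical(names(seqs), study$targets$gene_id)
  expect_identical(unname(as.character(seqs)),
                   unname(as.character(study$seqs)))
  cd <- read_counts(study$paths$counts, study$paths$design)
  expect_identical(cd$counts, study$counts)
  ann <- read_annotations(study$paths$annotations)
  expect_setequal(ann$gene_id, study$annotations$gene_id)
  slim <- read_slim_terms(study$paths$slim)
  expect_setequal(slim, study$ontology$slim)
})
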