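#' @title Synthetic study generator
#'
#' @description
#' Generates inputs with the statistical structure the analysis assumes:
#' per-gene CpG O/E targets drawn from a two-component Gaussian mixture,
#' transcript sequences realizing those targets through a first-order
#' Markov chain, component-biased GO annotations, and negative-binomial
#' counts for a 2 origin x 2 treatment x n replicate design in which the
#' probability that a gene responds rises with its CpG O/E. A truth table
#' accompanies every simulation so recovery can be scored.
#'
#' @name synthetic-data
NULL

#' Default simulation configuration
#'
#' The defaults mirror the conditions of a two-seagrass heat-stress study:
#' mixture parameters of the *P. oceanica* CpG O/E fit, lognormal gene
#' lengths with median 930 bp, GC content 0.41, a 2 x 2 x 3 design, and a
#' logistic CpG-to-responsiveness link with slope 3 on the logit scale.
#'
#' @param n_genes Number of genes.
#' @param mixture List with `lambda`, `mu`, `sigma` (2 components each).
#' @param length_meanlog,length_sdlog Lognormal gene-length parameters
#'   (median `exp(meanlog)`); lengths are truncated below at `min_length`.
#' @param min_length Minimum simulated gene length (bp).
#' @param gc GC content of the base composition.
#' @param oe_bounds Truncation bounds for the CpG O/E targets, keeping the
#'   ratio's domain valid.
#' @param de_a,de_b Intercept and slope of the logistic link
#'   `P(responsive) = plogis(de_a + de_b * target_oe)`, applied
#'   independently to the origin and treatment responses.
#' @param effect_mean,effect_sd Mean and sd of the |log2 fold change| of
#'   responsive genes (sign random).
#' @param phi Negative-binomial dispersion (0 = Poisson).
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline expression.
#' @param depth_range Uniform range of per-sample depth factors.
#' @param n_reps Replicates per origin x treatment cell.
#' @param annot_bias Odds multiplier tying constitutive terms to low-CpG
#'   genes (and responsive terms to high-CpG genes).
#' @param seed Integer seed fixing all randomness.
#' @return A named list (class `sim_config`).
#' @export
sim_config <- function(n_genes = 10000L,
                       mixture = list(lambda = c(0.661, 0.339),
                                      mu = c(0.476, 0.650),
                                      sigma = c(0.127, 0.214)),
                       length_meanlog = log(930), length_sdlog = 0.35,
                       min_length = 200L,
                       gc = 0.41,
                       oe_bounds = c(0.05, 2.0),
                       de_a = -4, de_b = 3,
                       effect_mean = 2, effect_sd = 0.5,
                       phi = 0.2,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       depth_range = c(0.8, 1.25),
                       n_reps = 3L,
                       annot_bias = 3,
                       seed = 1L) {
  stopifnot(abs(sum(mixture$lambda) - 1) < 1e-9, phi >= 0,
            min_length >= 200L, n_reps >= 2L)
  structure(as.list(environment()), class = "sim_config")
}

#' Draw per-gene CpG O/E targets from the mixture
#'
#' Component membership is drawn with probability lambda and the value from
#' the component's Gaussian, truncated to `oe_bounds` by resampling.
#'
#' @param cfg A [sim_config()].
#' @return data.frame `gene_id`, `target_oe`, `true_component`
#'   (`low`/`high`).
#' @export
simulate_cpg_targets <- function(cfg) {
  n <- cfg$n_genes
  comp <- 1L + rbinom(n, 1L, cfg$mixture$lambda[2L])
  x <- rnorm(n, cfg$mixture$mu[comp], cfg$mixture$sigma[comp])
  bad <- which(x < cfg$oe_bounds[1L] | x > cfg$oe_bounds[2L])
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), cfg$mixture$mu[comp[bad]],
                    cfg$mixture$sigma[comp[bad]])
    bad <- bad[x[bad] < cfg$oe_bounds[1L] | x[bad] > cfg$oe_bounds[2L]]
  }
  data.frame(gene_id = sprintf("g%05d", seq_len(n)),
             target_oe = x,
             true_component = c("low", "high")[comp],
             stringsAsFactors = FALSE)
}

#' Simulate transcript sequences realizing CpG O/E targets
#'
#' First-order Markov chain: outside C-states the next base follows the
#' base composition; after a C the probability of G is calibrated so that
#' the expected CpG O/E of long sequences equals the target. (The naive
#' choice `target_oe * pi_G` under-disperses the realized ratios because
#' suppressing CG transitions also shifts the chain's stationary C and G
#' frequencies; the calibration solves the stationary-frequency fixed
#' point so that `P(G|C) = target_oe * pi_G_stationary`, clipped at
#' `max_cg_prob`.)
#'
#' @param targets data.frame from [simulate_cpg_targets()] (or with
#'   columns `gene_id`, `target_oe`).
#' @param cfg A [sim_config()] supplying lengths and base composition.
#' @param lengths Optional integer vector overriding the lognormal draw.
#' @param max_cg_prob Clip on the C-to-G transition probability.
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_sequences <- function(targets, cfg, lengths = NULL,
                               max_cg_prob = 0.95) {
  pi <- base_composition(cfg$gc)
  if (any(targets$target_oe * pi[["G"]] >= 1))
    stop("infeasible C->G transition: target_oe * pi_G >= 1")
  if (is.null(lengths)) {
    lengths <- pmax(cfg$min_length,
                    round(rlnorm(nrow(targets), cfg$length_meanlog,
                                 cfg$length_sdlog)))
  }
  q <- calibrate_cg_prob(targets$target_oe, pi, max_cg_prob)
  seqs <- markov_sequences(as.integer(lengths), q, as.numeric(pi))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- targets$gene_id
  out
}

# Solve for the C->G transition probability q such that the chain's
# stationary frequencies give CpG O/E = q / pi_G_stationary = target.
# Stationary C and G frequencies under the two-row chain:
#   pi_C' = (1 - pi_C') pi_C + pi_C' (1 - q) pi_C / (1 - pi_G)
#   pi_G' = (1 - pi_C') pi_G + pi_C' q
# Iterated to a fixed point (vectorized over genes; converges in a
# handful of steps).
calibrate_cg_prob <- function(target_oe, pi, max_cg_prob) {
  piC <- pi[["C"]]; piG <- pi[["G"]]
  q <- pmin(pmax(target_oe * piG, 0), max_cg_prob)
  for (it in 1:50) {
    piC_st <- piC / (1 + piC - (1 - q) * piC / (1 - piG))
    piG_st <- (1 - piC_st) * piG + piC_st * q
    q_new <- pmin(pmax(target_oe * piG_st, 0), max_cg_prob)
    if (max(abs(q_new - q)) < 1e-12) {
      q <- q_new
      break
    }
    q <- q_new
  }
  q
}

base_composition <- function(gc) {
  stopifnot(gc > 0, gc < 1)
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

#' Term pools for the annotation generator
#'
#' Nineteen broad biological-process terms split into a "constitutive"
#' pool (housekeeping-like processes, tied to the low-CpG component) and a
#' "responsive" pool (inducible processes, tied to the high-CpG
#' component).
#'
#' @return List with character vectors `constitutive` and `responsive`.
#' @export
slim_term_pools <- function() {
  list(
    constitutive = c(
      "protein metabolic process", "cell cycle", "DNA metabolic process",
      "regulation of gene expression", "signaling",
      "RNA metabolic process", "chromosome organization",
      "cellular component organization", "cell division"),
    responsive = c(
      "translation", "response to stress", "response to stimulus",
      "photosynthesis", "response to abiotic stimulus", "transport",
      "carbohydrate metabolic process", "lipid metabolic process",
      "catabolic process",
      "generation of precursor metabolites and energy"))
}

#' Build a toy is_a ontology around the slim terms
#'
#' Each slim term gets `n_children` child terms and one grandchild (under
#' the first child), giving annotation terms one or two is_a hops from
#' their slim ancestor — enough to exercise ancestor-closure mapping.
#'
#' @param pools Term pools from [slim_term_pools()].
#' @param n_children Children per slim term.
#' @return List with `edges` (data.frame `child`, `parent`), `slim`
#'   (character vector) and `leaves_of` (slim term -> descendant terms,
#'   self included).
#' @export
simulate_ontology <- function(pools = slim_term_pools(), n_children = 3L) {
  slim <- unlist(pools, use.names = FALSE)
  edges <- list()
  leaves_of <- list()
  for (tm in slim) {
    children <- sprintf("%s/child_%d", tm, seq_len(n_children))
    grandchild <- sprintf("%s/grandchild", tm)
    edges[[tm]] <- data.frame(
      child = c(children, grandchild),
      parent = c(rep(tm, n_children), children[1L]),
      stringsAsFactors = FALSE)
    leaves_of[[tm]] <- c(tm, children, grandchild)
  }
  list(edges = do.call(rbind, c(edges, list(make.row.names = FALSE))),
       slim = slim, leaves_of = leaves_of)
}

#' Simulate component-biased gene annotations
#'
#' Every gene receives at least one term; low-component genes draw
#' constitutive terms with their odds multiplied by `bias`, high-component
#' genes likewise for responsive terms (`bias = 1` removes the
#' association). With an ontology, each drawn slim term is replaced by a
#' uniformly chosen descendant (possibly itself) so the annotations
#' exercise slim mapping.
#'
#' @param components Character vector (`low`/`high`) named by gene id, or
#'   a targets data.frame from [simulate_cpg_targets()].
#' @param pools Term pools (see [slim_term_pools()]).
#' @param bias Odds multiplier >= 1.
#' @param ontology Optional result of [simulate_ontology()].
#' @param mean_extra_terms Mean number of additional terms per gene
#'   (Poisson).
#' @return data.frame `gene_id`, `term`.
#' @export
simulate_annotations <- function(components, pools = slim_term_pools(),
                                 bias = 3, ontology = NULL,
                                 mean_extra_terms = 1) {
  if (is.data.frame(components))
    components <- setNames(components$true_component, components$gene_id)
  if (length(pools$constitutive) == 0L || length(pools$responsive) == 0L)
    stop("term pools must be non-empty")
  if (bias < 1) stop("bias must be >= 1")
  terms <- c(pools$constitutive, pools$responsive)
  w_const <- c(rep(bias, length(pools$constitutive)),
               rep(1, length(pools$responsive)))
  w_resp <- c(rep(1, length(pools$constitutive)),
              rep(bias, length(pools$responsive)))
  n_terms <- 1L + rpois(length(components), mean_extra_terms)
  n_terms <- pmin(n_terms, length(terms))
  picked <- lapply(seq_along(components), function(i) {
    w <- if (components[i] == "low") w_const else w_resp
    sample(terms, n_terms[i], replace = FALSE, prob = w)
  })
  ann <- data.frame(gene_id = rep(names(components), n_terms),
                    term = unlist(picked, use.names = FALSE),
                    stringsAsFactors = FALSE)
  if (!is.null(ontology)) {
    ann$term <- vapply(ann$term, function(tm) {
      leaves <- ontology$leaves_of[[tm]]
      leaves[sample.int(length(leaves), 1L)]
    }, "")
  }
  rownames(ann) <- NULL
  ann
}

#' Simulate a count matrix with CpG-linked differential expression
#'
#' Each gene is origin-responsive with probability
#' `plogis(de_a + de_b * target_oe)` and, independently,
#' treatment-responsive with the same link; responsive genes receive a
#' random-signed log2 effect. Counts are negative-binomial around
#' `baseline * depth * 2^effect` for the affected samples (warm origin /
#' heated treatment).
#'
#' @param targets data.frame from [simulate_cpg_targets()].
#' @param cfg A [sim_config()].
#' @return List with `counts` (integer matrix), `design` (data.frame) and
#'   `truth` (per-gene responsiveness flags and effects).
#' @export
simulate_counts <- function(targets, cfg) {
  n <- nrow(targets)
  design <- expand.grid(replicate = seq_len(cfg$n_reps),
                        treatment = c("control", "heated"),
                        origin = c("cold", "warm"),
                        stringsAsFactors = FALSE)
  design <- design[, c("origin", "treatment", "replicate")]
  design$sample_id <- sprintf("%s_%s_%d", design$origin, design$treatment,
                              design$replicate)
  design <- design[, c("sample_id", "origin", "treatment", "replicate")]

  p_resp <- plogis(cfg$de_a + cfg$de_b * targets$target_oe)
  origin_resp <- rbinom(n, 1L, p_resp) == 1L
  treat_resp <- rbinom(n, 1L, p_resp) == 1L
  rand_effect <- function(active) {
    e <- numeric(n)
    k <- sum(active)
    if (k > 0L)
      e[active] <- sample(c(-1, 1), k, replace = TRUE) *
        rnorm(k, cfg$effect_mean, cfg$effect_sd)
    e
  }
  origin_fc <- rand_effect(origin_resp)
  treat_fc <- rand_effect(treat_resp)

  baseline <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  depth <- runif(nrow(design), cfg$depth_range[1L], cfg$depth_range[2L])
  mu <- outer(baseline, depth) *
    2^(origin_fc %o% as.numeric(design$origin == "warm")) *
    2^(treat_fc %o% as.numeric(design$treatment == "heated"))
  counts <- if (cfg$phi > 0) {
    matrix(rnbinom(length(mu), size = 1 / cfg$phi, mu = mu), nrow = n)
  } else {
    matrix(rpois(length(mu), mu), nrow = n)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(targets$gene_id, design$sample_id)
  truth <- data.frame(gene_id = targets$gene_id,
                      target_oe = targets$target_oe,
                      true_component = targets$true_component,
                      origin_responsive = origin_resp,
                      origin_log2fc = origin_fc,
                      treatment_responsive = treat_resp,
                      treatment_log2fc = treat_fc,
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Chains the target, sequence, annotation and count generators under one
#' seed, optionally writing every artifact in the pipeline's input formats
#' (FASTA, annotation/ontology/slim TSVs, counts/design TSVs, truth TSV).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `seqs`, `targets`, `annotations`, `ontology`,
#'   `counts`, `design`, `truth` and (when written) `paths`.
#' @export
simulate_study <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  targets <- simulate_cpg_targets(cfg)
  seqs <- simulate_sequences(targets, cfg)
  ontology <- simulate_ontology()
  annotations <- simulate_annotations(targets, bias = cfg$annot_bias,
                                      ontology = ontology)
  sim <- simulate_counts(targets, cfg)
  out <- list(seqs = seqs, targets = targets, annotations = annotations,
              ontology = ontology, counts = sim$counts,
              design = sim$design, truth = sim$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "transcripts.fasta"),
      annotations = file.path(dir, "annotations.tsv"),
      ontology = file.path(dir, "ontology_edges.tsv"),
      slim = file.path(dir, "slim_terms.txt"),
      counts = file.path(dir, "counts.tsv"),
      design = file.path(dir, "design.tsv"),
      truth = file.path(dir, "truth.tsv"))
    Biostrings::writeXStringSet(seqs, paths$fasta)
    write.table(annotations, paths$annotations, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(ontology$edges, paths$ontology, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeLines(ontology$slim, paths$slim)
    counts_df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                            check.names = FALSE, stringsAsFactors = FALSE)
    write.table(counts_df, paths$counts, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$design, paths$design, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_tsv(sim$truth, paths$truth)
    out$paths <- paths
  }
  out
}
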