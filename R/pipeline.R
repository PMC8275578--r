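#' Run the full CpG / mixture / enrichment / DE / flexibility pipeline
#'
#' Chains every analysis stage from a single configuration (a YAML file or
#' an equivalent nested list): profile CpG O/E from sequences, fit the 1-
#' and 2-component mixtures and classify genes at the density
#' intersection, test GO-slim component enrichment, run the
#' differential-expression contrasts, and produce the quantile-bin
#' frequency/magnitude analyses. Inputs come either from files (an
#' `inputs` block) or from the synthetic generator (a `simulate` block).
#' All numeric artifacts are written as TSV (6 significant digits) plus a
#' JSON run summary carrying full double precision; a fixed seed makes the
#' numeric outputs byte-identical across runs.
#'
#' Configuration keys: `seed`, `out_dir`, one of `simulate` (overrides for
#' [sim_config()]) or `inputs` (`fasta`, `annotations`, `ontology`,
#' `slim`, `counts`, `design`), optional `stages` (subset of `cpg`,
#' `mixture`, `enrich`, `de`, `flexibility`), and per-stage settings
#' (`cpg`: `min_length`, `max_oe`; `mixture`: `n_starts`, `tol`,
#' `max_iter`; `de`: `contrasts`, `alpha`, `min_cpm`, `min_samples`;
#' `flexibility`: `freq_bins`, `mag_bins`).
#'
#' @param config Path to a YAML configuration file, or a nested list.
#' @return The run summary (the content of `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- pipeline_defaults(config)
  preflight(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  cat(sprintf("pipeline started (seed %d)\n", cfg$seed), file = log_path)
  set.seed(cfg$seed)

  state <- new.env(parent = emptyenv())
  summary <- list(seed = cfg$seed, stages = cfg$stages)

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    cat(sprintf("stage %-12s %.2fs\n", name,
                proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    res
  }

  # -- inputs -------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    study <- run_stage("simulate", function()
      simulate_study(do.call(sim_config, sim_args), dir = cfg$out_dir))
    state$seqs <- study$seqs
    state$annotations <- study$annotations
    state$ontology_edges <- study$ontology$edges
    state$slim <- study$ontology$slim
    state$counts <- study$counts
    state$design <- study$design
    summary$n_genes_input <- length(study$seqs)
  } else {
    inp <- cfg$inputs
    run_stage("read-inputs", function() {
      if (!is.null(inp$fasta)) state$seqs <- read_fasta(inp$fasta)
      if (!is.null(inp$annotations))
        state$annotations <- read_annotations(inp$annotations)
      if (!is.null(inp$ontology))
        state$ontology_edges <- read_ontology_edges(inp$ontology)
      if (!is.null(inp$slim)) state$slim <- read_slim_terms(inp$slim)
      if (!is.null(inp$counts)) {
        cd <- read_counts(inp$counts, inp$design)
        state$counts <- cd$counts
        state$design <- cd$design
      }
      invisible(NULL)
    })
    summary$n_genes_input <- length(state$seqs)
  }

  # -- CpG profiling ------------------------------------------------------
  if ("cpg" %in% cfg$stages) {
    profile <- run_stage("cpg", function() {
      pr <- profile_transcriptome(state$seqs,
                                  min_length = cfg$cpg$min_length,
                                  max_oe = cfg$cpg$max_oe, quiet = TRUE)
      write_cpg_profile(pr, file.path(cfg$out_dir, "cpg_profile.tsv"))
      pr
    })
    state$profile <- profile
    summary$n_genes_profiled <- nrow(profile)
    summary$n_genes_excluded <- nrow(attr(profile, "excluded"))
    summary$mean_cpg_oe <- mean(profile$cpg_oe)
  }

  # -- mixture + classification ------------------------------------------
  if ("mixture" %in% cfg$stages) {
    mix <- run_stage("mixture", function() {
      x <- state$profile$cpg_oe
      fit1 <- fit_single_gaussian(x)
      fit2 <- fit_mixture_em(x, k = 2L, tol = cfg$mixture$tol,
                             max_iter = cfg$mixture$max_iter,
                             n_starts = cfg$mixture$n_starts)
      sel <- select_model(fit1, fit2)
      thr <- component_intersection(fit2)
      split <- classify_genes(state$profile, thr)
      write_mixture_report(fit1, fit2, sel, thr,
                           file.path(cfg$out_dir, "mixture_report.tsv"))
      write_tsv(split$genes,
                file.path(cfg$out_dir, "classification.tsv"))
      list(fit1 = fit1, fit2 = fit2, sel = sel, thr = thr, split = split)
    })
    state$split <- mix$split
    state$threshold <- mix$thr
    summary$mixture <- list(
      lambda = mix$fit2$lambda, mu = mix$fit2$mu, sigma = mix$fit2$sigma,
      loglik_k1 = mix$fit1$loglik, loglik_k2 = mix$fit2$loglik,
      bic_k1 = mix$fit1$bic, bic_k2 = mix$fit2$bic,
      selected_k = mix$sel$selected_k, threshold = mix$thr,
      n_low = mix$split$n_low, n_high = mix$split$n_high,
      frac_depleted = mix$split$frac_depleted)
  }

  # -- GO-slim enrichment -------------------------------------------------
  if ("enrich" %in% cfg$stages) {
    enr <- run_stage("enrich", function() {
      slim_map <- map_to_slim(state$annotations, state$ontology_edges,
                              state$slim)
      summ <- category_cpg_summary(slim_map, state$profile)
      enrich <- fisher_enrichment(state$split, slim_map,
                                  alpha = cfg$de$alpha)
      write_tsv(summ, file.path(cfg$out_dir, "category_summary.tsv"))
      write_tsv(enrich, file.path(cfg$out_dir, "enrichment.tsv"))
      list(map = slim_map, summary = summ, enrich = enrich)
    })
    state$enrichment <- enr$enrich
    summary$enrichment <- list(
      n_terms = length(unique(enr$enrich$term)),
      n_unassigned_genes = length(enr$map$unassigned),
      n_significant = sum(enr$enrich$significant))
  }

  # -- differential expression -------------------------------------------
  if ("de" %in% cfg$stages) {
    de_list <- run_stage("de", function() {
      res <- lapply(cfg$de$contrasts, function(ct) {
        de <- run_contrast(state$counts, state$design, ct,
                           alpha = cfg$de$alpha,
                           min_cpm = cfg$de$min_cpm,
                           min_samples = cfg$de$min_samples, quiet = TRUE)
        write_tsv(as.data.frame(de),
                  file.path(cfg$out_dir, paste0("de_", ct, ".tsv")))
        de
      })
      names(res) <- cfg$de$contrasts
      res
    })
    state$de <- de_list
    summ_de <- de_summary(de_list, summary$n_genes_input)
    summary$de <- lapply(seq_len(nrow(summ_de)), function(i)
      as.list(summ_de[i, -1L]))
    names(summary$de) <- summ_de$contrast
  }

  # -- flexibility --------------------------------------------------------
  if ("flexibility" %in% cfg$stages) {
    flex <- run_stage("flexibility", function() {
      lapply(names(state$de), function(ct) {
        de <- state$de[[ct]]
        shared <- state$profile[state$profile$gene_id %in% de$gene_id, ]
        bins25 <- quantile_bins(shared, cfg$flexibility$freq_bins)
        bins12 <- quantile_bins(shared, cfg$flexibility$mag_bins)
        freq <- bin_frequency(bins25, de, threshold = state$threshold)
        mag <- bin_magnitude(bins12, de, threshold = state$threshold)
        contrasts <- component_contrast(freq$table, state$split, de)
        write_tsv(freq$table,
                  file.path(cfg$out_dir,
                            paste0("bins_frequency_", ct, ".tsv")))
        write_tsv(mag$table,
                  file.path(cfg$out_dir,
                            paste0("bins_magnitude_", ct, ".tsv")))
        list(freq = freq, mag = mag, contrasts = contrasts)
      }) |> setNames(names(state$de))
    })
    summary$flexibility <- lapply(flex, function(fl) {
      list(
        freq_r = if (is.null(fl$freq$correlation)) NA else
          fl$freq$correlation$estimate,
        freq_p = if (is.null(fl$freq$correlation)) NA else
          fl$freq$correlation$p_value,
        mag_pearson_r = if (is.null(fl$mag$pearson)) NA else
          fl$mag$pearson$estimate,
        mag_spearman_rho = if (is.null(fl$mag$spearman)) NA else
          fl$mag$spearman$estimate,
        mag_anova_p = fl$mag$anova$p_value,
        comp_freq_p = if (is.null(fl$contrasts$frequency)) NA else
          fl$contrasts$frequency$p_value,
        comp_mag_p = fl$contrasts$magnitude$p_value)
    })
    if (all(c("treatment_cold", "treatment_warm") %in% names(flex))) {
      slopes <- population_slopes(
        flex$treatment_cold$freq$table, flex$treatment_warm$freq$table)
      summary$population_slopes <- slopes
    }
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  cat("pipeline finished\n", file = log_path, append = TRUE)
  invisible(summary)
}

pipeline_defaults <- function(config) {
  def <- list(
    seed = 1L,
    out_dir = NULL,
    simulate = NULL,
    inputs = NULL,
    stages = NULL,
    cpg = list(min_length = 201L, max_oe = NULL),
    mixture = list(n_starts = 10L, tol = 1e-8, max_iter = 2000L),
    de = list(contrasts = c("origin", "treatment_all", "treatment_cold",
                            "treatment_warm"),
              alpha = 0.05, min_cpm = 1, min_samples = 3L),
    flexibility = list(freq_bins = 25L, mag_bins = 12L))
  cfg <- utils::modifyList(def, config)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$stages)) {
    cfg$stages <- if (!is.null(cfg$simulate)) {
      c("cpg", "mixture", "enrich", "de", "flexibility")
    } else {
      st <- character(0)
      if (!is.null(cfg$inputs$fasta)) st <- c(st, "cpg", "mixture")
      if (!is.null(cfg$inputs$annotations)) st <- c(st, "enrich")
      if (!is.null(cfg$inputs$counts)) st <- c(st, "de")
      if (all(c("cpg", "de") %in% c(st))) st <- c(st, "flexibility")
      st
    }
  }
  cfg
}

preflight <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("config must set 'out_dir'")
  if (is.null(cfg$simulate) == is.null(cfg$inputs))
    stop("config must have exactly one of 'simulate' or 'inputs'")
  stage_needs <- list(
    cpg = "fasta", mixture = "fasta",
    enrich = c("fasta", "annotations", "slim"),
    de = c("counts", "design"),
    flexibility = c("fasta", "counts", "design"))
  if ("enrich" %in% cfg$stages && !"mixture" %in% cfg$stages)
    stop("pre-flight: stage 'enrich' requires stage 'mixture'")
  if ("flexibility" %in% cfg$stages &&
      !all(c("cpg", "mixture", "de") %in% cfg$stages))
    stop("pre-flight: stage 'flexibility' requires cpg, mixture and de")
  if (!is.null(cfg$inputs)) {
    # first make sure every requested stage has its inputs configured,
    # then that the configured files exist
    for (st in intersect(cfg$stages, names(stage_needs))) {
      need <- stage_needs[[st]]
      missing <- need[vapply(need, function(k)
        is.null(cfg$inputs[[k]]), TRUE)]
      if (length(missing) > 0L)
        stop("pre-flight: stage '", st, "' requires input(s): ",
             paste(missing, collapse = ", "))
    }
    for (st in intersect(cfg$stages, names(stage_needs))) {
      for (k in stage_needs[[st]])
        if (!file.exists(cfg$inputs[[k]]))
          stop("pre-flight: input file for '", k, "' not found: ",
               cfg$inputs[[k]])
    }
  }
  invisible(cfg)
}
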