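#' Assign genes to equally sized CpG O/E quantile bins
#'
#' Genes are sorted by `(cpg_oe, gene_id)` (the id breaking ties
#' deterministically) and split into `n_bins` contiguous groups whose sizes
#' differ by at most one; remainders go to the lowest bins.
#'
#' @param records CpG profile data.frame (`gene_id`, `cpg_oe`).
#' @param n_bins Number of quantile bins.
#' @return data.frame `gene_id`, `cpg_oe`, `bin` (1 = lowest CpG O/E).
#' @export
quantile_bins <- function(records, n_bins) {
  n <- nrow(records)
  if (n < n_bins)
    stop("cannot form ", n_bins, " bins from ", n, " genes")
  ord <- order(records$cpg_oe, records$gene_id)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  out <- data.frame(gene_id = records$gene_id[ord],
                    cpg_oe = records$cpg_oe[ord],
                    bin = rep(seq_len(n_bins), sizes),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

bin_base_table <- function(bins, threshold = NULL) {
  spl <- split(bins$cpg_oe, bins$bin)
  tab <- data.frame(bin = as.integer(names(spl)),
                    n_genes = lengths(spl),
                    mean_cpg_oe = vapply(spl, mean, 0),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$bin), , drop = FALSE]
  if (!is.null(threshold))
    tab$component <- ifelse(tab$mean_cpg_oe < threshold, "low", "high")
  rownames(tab) <- NULL
  tab
}

#' Per-bin DEG frequency and its correlation with CpG O/E
#'
#' Counts DEGs per quantile bin and correlates (Pearson) the per-bin DEG
#' count with the bin's mean CpG O/E.
#'
#' @param bins Bin assignment from [quantile_bins()] (typically 25 bins).
#' @param de A `cpg_de` table (only genes present in both are used).
#' @param threshold Optional component threshold used to label each bin by
#'   its mean CpG O/E.
#' @return List with `table` (per-bin `n_genes`, `mean_cpg_oe`, `n_deg`,
#'   optional `component`) and `correlation` (Pearson across bins, or
#'   `NULL` with a message when there are no DEGs at all).
#' @export
bin_frequency <- function(bins, de, threshold = NULL) {
  merged <- merge(bins, de[, c("gene_id", "is_deg")], by = "gene_id")
  if (nrow(merged) == 0L) stop("no genes shared between bins and DE table")
  tab <- bin_base_table(bins[bins$gene_id %in% merged$gene_id, ],
                        threshold)
  deg_by_bin <- tapply(merged$is_deg, merged$bin, sum)
  tab$n_deg <- as.integer(deg_by_bin[as.character(tab$bin)])
  tab$n_deg[is.na(tab$n_deg)] <- 0L
  if (nrow(tab) < 3L) stop("need at least 3 populated bins")
  corr <- if (sum(tab$n_deg) == 0L) {
    message("bin_frequency: no DEGs; correlation undefined")
    NULL
  } else if (sd(tab$n_deg) == 0) {
    message("bin_frequency: constant DEG counts; correlation undefined")
    NULL
  } else {
    correlation_test(tab$mean_cpg_oe, tab$n_deg, "pearson")
  }
  list(table = tab, correlation = corr)
}

#' Per-bin expression magnitude and its trend across CpG O/E
#'
#' Mean absolute magnitude (|log10 expression ratio|) +/- standard error
#' per quantile bin (typically 12 bins); Pearson and Spearman correlations
#' of the per-bin means against mean CpG O/E, and a one-way ANOVA of the
#' per-gene magnitudes across bins (bins with fewer than 2 genes are
#' excluded from the ANOVA with a warning).
#'
#' @param bins Bin assignment from [quantile_bins()].
#' @param de A `cpg_de` table with a `magnitude` column.
#' @param threshold Optional component threshold for bin labels.
#' @return List with `table` (adds `mean_magnitude`, `se_magnitude`),
#'   `pearson`, `spearman` (or `NULL` when degenerate) and `anova`.
#' @export
bin_magnitude <- function(bins, de, threshold = NULL) {
  merged <- merge(bins, de[, c("gene_id", "magnitude")], by = "gene_id")
  if (nrow(merged) == 0L) stop("no genes shared between bins and DE table")
  if (any(!is.finite(merged$magnitude)))
    stop("magnitudes must be finite")
  merged$abs_mag <- abs(merged$magnitude)
  tab <- bin_base_table(merged[, c("gene_id", "cpg_oe", "bin")], threshold)
  spl <- split(merged$abs_mag, merged$bin)
  tab$mean_magnitude <- vapply(spl, mean, 0)[as.character(tab$bin)]
  tab$se_magnitude <- vapply(spl, function(v)
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
    0)[as.character(tab$bin)]
  degenerate <- sd(tab$mean_magnitude) == 0
  if (degenerate)
    message("bin_magnitude: constant bin means; correlations undefined")
  pear <- if (degenerate) NULL else
    correlation_test(tab$mean_cpg_oe, tab$mean_magnitude, "pearson")
  spear <- if (degenerate) NULL else
    correlation_test(tab$mean_cpg_oe, tab$mean_magnitude, "spearman")
  groups <- spl[lengths(spl) >= 2L]
  if (length(groups) < length(spl))
    warning(length(spl) - length(groups),
            " bin(s) with < 2 genes excluded from the ANOVA")
  aov_res <- anova_oneway(groups)
  list(table = tab, pearson = pear, spearman = spear, anova = aov_res)
}

#' Low- vs high-CpG component contrasts
#'
#' Welch t-tests comparing (i) per-bin DEG counts between bins assigned to
#' the low and high components and (ii) per-gene absolute magnitudes
#' between low- and high-component genes.
#'
#' @param bin_table Frequency bin table (from [bin_frequency()]) with a
#'   `component` column.
#' @param split `cpg_split` from [classify_genes()].
#' @param de `cpg_de` table with `magnitude`.
#' @return List with `frequency` (t-test on bin DEG counts, or `NULL` with
#'   a message when a component has fewer than 2 bins), `magnitude`
#'   (t-test on gene |magnitude|) and per-component summaries.
#' @export
component_contrast <- function(bin_table, split, de) {
  stopifnot(inherits(split, "cpg_split"))
  if (is.null(bin_table$component))
    stop("bin_table lacks a 'component' column; pass a threshold when binning")
  lo_bins <- bin_table$n_deg[bin_table$component == "low"]
  hi_bins <- bin_table$n_deg[bin_table$component == "high"]
  freq <- if (length(lo_bins) < 2L || length(hi_bins) < 2L) {
    message("component_contrast: a component has < 2 bins; ",
            "frequency test skipped")
    NULL
  } else {
    welch_t(lo_bins, hi_bins)
  }
  comp <- setNames(split$genes$component, split$genes$gene_id)
  de_comp <- comp[de$gene_id]
  mag <- abs(de$magnitude)
  lo_mag <- mag[de_comp == "low" & !is.na(de_comp)]
  hi_mag <- mag[de_comp == "high" & !is.na(de_comp)]
  if (length(lo_mag) < 2L || length(hi_mag) < 2L)
    stop("each component needs at least 2 genes with magnitudes")
  list(
    frequency = freq,
    magnitude = welch_t(lo_mag, hi_mag),
    summary = data.frame(
      component = c("low", "high"),
      n_bins = c(length(lo_bins), length(hi_bins)),
      mean_bin_deg = c(mean(lo_bins), mean(hi_bins)),
      sd_bin_deg = c(sd(lo_bins), sd(hi_bins)),
      n_genes = c(length(lo_mag), length(hi_mag)),
      mean_magnitude = c(mean(lo_mag), mean(hi_mag)),
      sd_magnitude = c(sd(lo_mag), sd(hi_mag)),
      stringsAsFactors = FALSE))
}

#' Compare DEG-frequency slopes between two populations
#'
#' OLS slope of per-bin DEG count against mean CpG O/E for each
#' population's bin table, and their ratio.
#'
#' @param bin_table_a,bin_table_b Frequency bin tables sharing the same
#'   number of bins.
#' @return List with `slope_a`, `slope_b`, `ratio` (`NA` with a message
#'   when `slope_b` is 0).
#' @export
population_slopes <- function(bin_table_a, bin_table_b) {
  if (nrow(bin_table_a) != nrow(bin_table_b))
    stop("bin tables must share the same number of bins")
  fa <- linear_fit(bin_table_a$mean_cpg_oe, bin_table_a$n_deg)
  fb <- linear_fit(bin_table_b$mean_cpg_oe, bin_table_b$n_deg)
  ratio <- if (fb$slope == 0) {
    message("population_slopes: second slope is 0; ratio undefined")
    NA_real_
  } else {
    fa$slope / fb$slope
  }
  list(slope_a = fa$slope, slope_b = fb$slope, ratio = ratio)
}
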