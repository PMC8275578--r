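#' @title Simplified negative-binomial differential expression
#'
#' @description
#' A documented, self-contained two-group pipeline: counts-per-million
#' expression filter, TMM between-sample normalization, method-of-moments
#' negative-binomial dispersion with shrinkage toward a common value, a
#' conditional exact NB test of equal group means, and Benjamini-Hochberg
#' FDR control. It deliberately trades the full GLM machinery of dedicated
#' DE packages for transparency; DE tables from any external tool can be
#' substituted via [import_de_table()].
#'
#' @name diffexpr
NULL

#' Counts-per-million
#'
#' @param counts Integer/numeric matrix, genes x samples.
#' @param lib_sizes Optional library sizes (default: column sums).
#' @return Matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Filter lowly expressed genes by CPM
#'
#' Keeps genes with CPM at or above `min_cpm` in at least `min_samples`
#' samples (the size of the smallest replicate group, by default 3).
#'
#' @param counts Count matrix, genes x samples (rownames = gene ids).
#' @param min_cpm CPM threshold (inclusive).
#' @param min_samples Minimum number of samples meeting the threshold.
#' @param quiet Suppress the kept/dropped message.
#' @return The filtered count matrix.
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = 3L,
                       quiet = FALSE) {
  x <- cpm(counts)
  keep <- rowSums(x >= min_cpm) >= min_samples
  if (!any(keep)) stop("all genes removed by the expression filter")
  if (!quiet)
    message("cpm_filter: kept ", sum(keep), " of ", length(keep), " genes")
  counts[keep, , drop = FALSE]
}

#' Trimmed mean of M-values normalization factors
#'
#' Weighted trimmed mean of per-gene log2 expression ratios against a
#' reference sample (the one whose 75th CPM percentile is closest to the
#' across-sample mean), trimming the `trim_m` tails of the M-values and the
#' `trim_a` tails of the average log intensities, with precision
#' (delta-method) weights. Factors are rescaled to geometric mean 1.
#'
#' @param counts Filtered count matrix, genes x samples.
#' @param trim_m Fraction trimmed from each M tail.
#' @param trim_a Fraction trimmed from each A tail.
#' @return Named numeric vector of scaling factors (one per sample).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be positive")
  q75 <- apply(cpm(counts, lib), 2L, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    tmm_pair(counts[, i], counts[, ref], lib[i], lib[ref], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) {
    warning("sample shares no positive genes with the reference; factor 1")
    return(1)
  }
  o <- obs[pos] / n_obs
  r <- ref[pos] / n_ref
  m <- log2(o / r)
  a <- 0.5 * log2(o * r)
  w <- (n_obs - obs[pos]) / (n_obs * obs[pos]) +
    (n_ref - ref[pos]) / (n_ref * ref[pos])
  fin <- is.finite(m) & is.finite(a) & is.finite(w)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  n <- length(m)
  if (n == 0L) return(1)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m, ties.method = "first") >= lo_m &
    rank(m, ties.method = "first") <= hi_m &
    rank(a, ties.method = "first") >= lo_a &
    rank(a, ties.method = "first") <= hi_a
  if (!any(keep)) return(1)
  2^(sum(w[keep] * m[keep]) / sum(w[keep]))
}

#' Method-of-moments NB dispersion with shrinkage
#'
#' Counts are scaled to a common effective library size; the per-gene
#' dispersion is the method-of-moments estimate
#' `phi_g = max(0, (s^2 - mu) / mu^2)` with the variance pooled within
#' groups, the common dispersion is the median over genes, and the tagwise
#' value shrinks the per-gene estimate toward the common one:
#' `phi_tag = (1 - w) * phi_g + w * phi_common`.
#'
#' @param counts Filtered count matrix.
#' @param groups Factor/character vector of group labels (one per sample),
#'   each group with >= 2 replicates.
#' @param factors Optional TMM factors (default: computed from `counts`).
#' @param shrink Shrinkage weight `w` toward the common dispersion.
#' @return List with `phi_gene` (raw per-gene), `phi_common`,
#'   `phi_tagwise`.
#' @export
estimate_dispersion <- function(counts, groups, factors = NULL,
                                shrink = 0.7) {
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("groups must have one label per sample")
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 replicates")
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts) * factors
  common_size <- exp(mean(log(eff)))
  y <- sweep(counts, 2L, eff, "/") * common_size

  glev <- unique(groups)
  idx <- lapply(glev, function(g) which(groups == g))
  n <- ncol(y)
  k <- length(glev)
  group_means <- vapply(idx, function(ii) rowMeans(y[, ii, drop = FALSE]),
                        numeric(nrow(y)))
  ssw <- rowSums(vapply(seq_along(idx), function(j)
    rowSums((y[, idx[[j]], drop = FALSE] - group_means[, j])^2),
    numeric(nrow(y))))
  s2 <- ssw / (n - k)
  mu <- rowMeans(y)
  phi_gene <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  phi_common <- median(phi_gene[mu > 0])
  phi_tagwise <- (1 - shrink) * phi_gene + shrink * phi_common
  list(phi_gene = phi_gene, phi_common = phi_common,
       phi_tagwise = setNames(phi_tagwise, rownames(counts)))
}

#' Conditional exact negative-binomial test
#'
#' Counts are scaled to the common effective library size and summed within
#' each group; conditional on the total, the low-group sum under the null
#' of equal means follows the convolution of two NB distributions (a
#' binomial when dispersion is 0). The two-sided p-value sums the
#' probabilities of all outcomes at most as probable as the observed one.
#'
#' @param counts Filtered count matrix.
#' @param group_a,group_b Column indices (or names) of the two groups.
#' @param factors TMM factors for all columns of `counts`.
#' @param phi Per-gene dispersion vector (recycled if scalar).
#' @return Numeric vector of per-gene two-sided p-values.
#' @export
nb_exact_test <- function(counts, group_a, group_b, factors, phi) {
  if (is.character(group_a)) group_a <- match(group_a, colnames(counts))
  if (is.character(group_b)) group_b <- match(group_b, colnames(counts))
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 samples")
  used <- c(group_a, group_b)
  eff <- (colSums(counts) * factors)[used]
  common_size <- exp(mean(log(eff)))
  y <- sweep(counts[, used, drop = FALSE], 2L,
             (colSums(counts) * factors)[used], "/") * common_size
  na <- length(group_a)
  nb <- length(group_b)
  sa <- round(rowSums(y[, seq_len(na), drop = FALSE]))
  sb <- round(rowSums(y[, na + seq_len(nb), drop = FALSE]))
  phi <- rep_len(phi, nrow(counts))
  vapply(seq_len(nrow(counts)), function(g)
    nb_exact_p(sa[g], sb[g], na, nb, phi[g]), 0)
}

nb_exact_p <- function(sa, sb, na, nb, phi) {
  tot <- sa + sb
  if (tot == 0) return(1)
  mu0 <- tot / (na + nb)  # common per-sample mean under the null
  support <- 0:tot
  if (tot > 50000) {
    # restrict to a wide window around the conditional mode (mass outside
    # is numerically negligible); always include the observed outcome
    ctr <- tot * na / (na + nb)
    sdv <- sqrt(tot * na * nb / (na + nb)^2 * (1 + phi * mu0))
    lo <- max(0, floor(min(ctr - 40 * sdv, sa)))
    hi <- min(tot, ceiling(max(ctr + 40 * sdv, sa)))
    support <- lo:hi
  }
  if (phi <= 0) {
    lp <- dpois(support, na * mu0, log = TRUE) +
      dpois(tot - support, nb * mu0, log = TRUE)
  } else {
    lp <- dnbinom(support, size = na / phi, mu = na * mu0, log = TRUE) +
      dnbinom(tot - support, size = nb / phi, mu = nb * mu0, log = TRUE)
  }
  lp <- lp - max(lp)
  pr <- exp(lp)
  p_obs <- pr[support == sa]
  sum(pr[pr <= p_obs * (1 + 1e-7)]) / sum(pr)
}

contrast_groups <- function(design, contrast) {
  sid <- design$sample_id
  switch(contrast,
    origin = list(a = sid[design$origin == "warm"],
                  b = sid[design$origin == "cold"],
                  label_a = "warm", label_b = "cold"),
    treatment_all = list(a = sid[design$treatment == "heated"],
                         b = sid[design$treatment == "control"],
                         label_a = "heated", label_b = "control"),
    treatment_cold = list(
      a = sid[design$origin == "cold" & design$treatment == "heated"],
      b = sid[design$origin == "cold" & design$treatment == "control"],
      label_a = "cold_heated", label_b = "cold_control"),
    treatment_warm = list(
      a = sid[design$origin == "warm" & design$treatment == "heated"],
      b = sid[design$origin == "warm" & design$treatment == "control"],
      label_a = "warm_heated", label_b = "warm_control"),
    stop("unknown contrast '", contrast, "'")
  )
}

#' Run one differential-expression contrast
#'
#' Chains the CPM filter, TMM factors, dispersion estimation, the exact NB
#' test and BH correction for one of the four standard contrasts. The fold
#' change is `log2` of the ratio of normalized group-mean CPMs and the
#' magnitude is `log10` of the same ratio, both with a pseudocount keeping
#' them finite; group a is the numerator (warm, or heated).
#'
#' @param counts Raw count matrix, genes x samples.
#' @param design Sample design data.frame (see [read_counts()]).
#' @param contrast One of `"origin"`, `"treatment_all"`,
#'   `"treatment_cold"`, `"treatment_warm"`.
#' @param alpha FDR threshold for the DEG flag.
#' @param min_cpm,min_samples Expression-filter settings.
#' @param pseudo_cpm Pseudocount (CPM units) for the ratio logs.
#' @param quiet Suppress filter messages.
#' @return data.frame of class `cpg_de` with `gene_id`, `mean_a`, `mean_b`
#'   (normalized CPM), `log2_fc`, `magnitude`, `p`, `fdr`, `is_deg`;
#'   attributes `contrast`, `alpha`, `n_a`, `n_b`, `n_total`.
#' @export
run_contrast <- function(counts, design, contrast, alpha = 0.05,
                         min_cpm = 1, min_samples = 3L, pseudo_cpm = 0.5,
                         quiet = FALSE) {
  grp <- contrast_groups(design, contrast)
  if (length(grp$a) < 2L || length(grp$b) < 2L)
    stop("contrast '", contrast, "' needs >= 2 samples per group")
  sub <- counts[, c(grp$a, grp$b), drop = FALSE]
  filt <- cpm_filter(sub, min_cpm = min_cpm, min_samples = min_samples,
                     quiet = quiet)
  factors <- tmm_factors(filt)
  groups <- rep(c("a", "b"), c(length(grp$a), length(grp$b)))
  disp <- estimate_dispersion(filt, groups, factors)
  p <- nb_exact_test(filt, seq_along(grp$a),
                     length(grp$a) + seq_along(grp$b),
                     factors, disp$phi_tagwise)
  norm_cpm <- cpm(filt, colSums(filt) * factors)
  mean_a <- rowMeans(norm_cpm[, seq_along(grp$a), drop = FALSE])
  mean_b <- rowMeans(norm_cpm[, length(grp$a) + seq_along(grp$b),
                              drop = FALSE])
  fdr <- bh_fdr(p)
  out <- data.frame(
    gene_id = rownames(filt),
    mean_a = mean_a, mean_b = mean_b,
    log2_fc = log2((mean_a + pseudo_cpm) / (mean_b + pseudo_cpm)),
    magnitude = log10((mean_a + pseudo_cpm) / (mean_b + pseudo_cpm)),
    p = p, fdr = fdr, is_deg = fdr < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("cpg_de", "data.frame"),
            contrast = contrast, alpha = alpha,
            n_a = length(grp$a), n_b = length(grp$b),
            label_a = grp$label_a, label_b = grp$label_b,
            n_total = nrow(counts))
}

#' Import a differential-expression table from an external tool
#'
#' Accepts any table with `gene_id`, `logFC` (log2), `p` and `fdr`
#' (`PValue`/`FDR` aliases recognized) so that downstream flexibility
#' analyses can run on the output of a dedicated DE package.
#'
#' @param x data.frame or path to a TSV.
#' @param alpha FDR threshold for the DEG flag.
#' @return A `cpg_de`-compatible data.frame (`magnitude` is the imported
#'   log2 fold change rescaled to log10).
#' @export
import_de_table <- function(x, alpha = 0.05) {
  df <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
  alias <- c(PValue = "p", FDR = "fdr", logFC = "log2_fc")
  for (nm in names(alias))
    if (nm %in% colnames(df) && !(alias[[nm]] %in% colnames(df)))
      colnames(df)[colnames(df) == nm] <- alias[[nm]]
  req <- c("gene_id", "log2_fc", "p", "fdr")
  miss <- setdiff(req, colnames(df))
  if (length(miss) > 0L)
    stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  df$magnitude <- df$log2_fc * log10(2)
  df$is_deg <- df$fdr < alpha
  structure(df, class = c("cpg_de", "data.frame"), alpha = alpha,
            contrast = "imported")
}

#' Summarize DEG counts across contrasts
#'
#' Reports, per contrast, the DEG count and its percentage against two
#' denominators: the genes passing the expression filter and, when
#' supplied, the full transcriptome gene count.
#'
#' @param de_list Named list of `cpg_de` tables.
#' @param n_transcriptome Optional total gene count of the transcriptome.
#' @return data.frame with `contrast`, `n_expressed`, `n_deg`,
#'   `pct_of_expressed` and `pct_of_transcriptome`.
#' @export
de_summary <- function(de_list, n_transcriptome = NA_integer_) {
  rows <- lapply(names(de_list), function(nm) {
    de <- de_list[[nm]]
    data.frame(contrast = nm, n_expressed = nrow(de),
               n_deg = sum(de$is_deg),
               pct_of_expressed = deg_percentage(sum(de$is_deg), nrow(de)),
               pct_of_transcriptome =
                 deg_percentage(sum(de$is_deg), n_transcriptome),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percentage of genes in a reference total
#'
#' @param n_deg Number of flagged genes.
#' @param n_total Denominator gene count.
#' @return Percentage (0-100 scale); `NA` for a missing denominator.
#' @export
deg_percentage <- function(n_deg, n_total) {
  if (is.na(n_total) || n_total <= 0) return(NA_real_)
  100 * n_deg / n_total
}
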