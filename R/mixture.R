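#' @title Gaussian mixture modelling of CpG O/E values
#'
#' @description
#' A transcriptome's CpG O/E distribution is modelled as a k-component
#' Gaussian mixture (k = 1 or 2). The two-component fit separates a
#' "low-CpG" component (CpG-depleted, biased toward historically
#' hypermethylated genes) from a "high-CpG" component; the point where the
#' two weighted component densities intersect provides an objective
#' classification threshold.
#'
#' @name mixture-model
NULL

new_mixfit <- function(k, lambda, mu, sigma, loglik, bic, n,
                       converged = TRUE, n_iter = 0L, loglik_trace = NULL) {
  ord <- order(mu)
  structure(
    list(k = as.integer(k), lambda = lambda[ord], mu = mu[ord],
         sigma = sigma[ord], loglik = loglik, bic = bic, n = as.integer(n),
         converged = converged, n_iter = as.integer(n_iter),
         loglik_trace = loglik_trace),
    class = "cpg_mixfit")
}

#' @export
print.cpg_mixfit <- function(x, ...) {
  cat(sprintf("%d-component Gaussian mixture (n = %s)\n", x$k,
              format(x$n, big.mark = ",")))
  for (j in seq_len(x$k))
    cat(sprintf("  comp-%d: lambda = %.3f, mu = %.3f, sigma = %.3f\n",
                j, x$lambda[j], x$mu[j], x$sigma[j]))
  cat(sprintf("  loglik = %.2f, BIC = %.2f, converged = %s (%d iterations)\n",
              x$loglik, x$bic, x$converged, x$n_iter))
  invisible(x)
}

#' Build a mixture-parameter object from known parameters
#'
#' Useful for computing classification thresholds from published mixture
#' parameters without refitting.
#'
#' @param lambda,mu,sigma Numeric vectors of equal length k (mixing
#'   proportions, means, standard deviations).
#' @return A `cpg_mixfit` object (log-likelihood and BIC are `NA`).
#' @export
mixture_params <- function(lambda, mu, sigma) {
  k <- length(mu)
  stopifnot(length(lambda) == k, length(sigma) == k,
            all(sigma > 0), all(lambda > 0))
  if (abs(sum(lambda) - 1) > 1e-6)
    stop("mixing proportions must sum to 1")
  new_mixfit(k, lambda, mu, sigma, NA_real_, NA_real_, NA_integer_)
}

n_mix_params <- function(k) if (k == 1L) 2L else 3L * k - 1L

mix_loglik <- function(x, lambda, mu, sigma) {
  k <- length(mu)
  lp <- vapply(seq_len(k), function(j)
    log(lambda[j]) + dnorm(x, mu[j], sigma[j], log = TRUE),
    numeric(length(x)))
  if (k == 1L) return(sum(lp))
  m <- pmax(lp[, 1L], lp[, 2L])
  sum(m + log(exp(lp[, 1L] - m) + exp(lp[, 2L] - m)))
}

#' Fit a single Gaussian (null model)
#'
#' Maximum-likelihood fit: mean and MLE standard deviation (divisor n).
#'
#' @param x Numeric vector of at least 10 finite values.
#' @param sigma_floor Lower bound on the standard deviation, guarding
#'   against degenerate (constant) input.
#' @return A `cpg_mixfit` with k = 1.
#' @export
fit_single_gaussian <- function(x, sigma_floor = 1e-4) {
  if (anyNA(x) || any(!is.finite(x))) stop("x contains non-finite values")
  n <- length(x)
  if (n < 10L) stop("insufficient data: need at least 10 values, got ", n)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / n)
  if (sigma < sigma_floor) {
    warning("degenerate variance; sigma clipped to floor ", sigma_floor)
    sigma <- sigma_floor
  }
  ll <- mix_loglik(x, 1, mu, sigma)
  new_mixfit(1L, 1, mu, sigma, ll, -2 * ll + n_mix_params(1L) * log(n), n)
}

em_iterate <- function(x, lambda, mu, sigma, tol, max_iter, sigma_floor,
                       trace = FALSE) {
  n <- length(x)
  ll_old <- -Inf
  ll_trace <- if (trace) numeric(0) else NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lp1 <- log(lambda[1L]) + dnorm(x, mu[1L], sigma[1L], log = TRUE)
    lp2 <- log(lambda[2L]) + dnorm(x, mu[2L], sigma[2L], log = TRUE)
    m <- pmax(lp1, lp2)
    denom <- m + log(exp(lp1 - m) + exp(lp2 - m))
    ll <- sum(denom)
    if (trace) ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && ll - ll_old < tol && iter > 1L) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    ll_old <- ll
    r1 <- exp(lp1 - denom)
    s1 <- sum(r1)
    s2 <- n - s1
    if (s1 < 1e-10 || s2 < 1e-10) break  # component collapse
    mu_new <- c(sum(r1 * x) / s1, sum((1 - r1) * x) / s2)
    sigma_new <- sqrt(c(sum(r1 * (x - mu_new[1L])^2) / s1,
                        sum((1 - r1) * (x - mu_new[2L])^2) / s2))
    sigma_new <- pmax(sigma_new, sigma_floor)
    lambda <- c(s1, s2) / n
    mu <- mu_new
    sigma <- sigma_new
  }
  list(lambda = lambda, mu = mu, sigma = sigma, loglik = ll,
       converged = converged, n_iter = iter, loglik_trace = ll_trace)
}

em_start <- function(x, split_q) {
  cut <- quantile(x, split_q, names = FALSE)
  lo <- x <= cut
  if (sum(lo) < 2L || sum(!lo) < 2L) {
    lo <- x <= median(x)
  }
  list(lambda = c(mean(lo), mean(!lo)),
       mu = c(mean(x[lo]), mean(x[!lo])),
       sigma = pmax(c(sd(x[lo]), sd(x[!lo])), 1e-3))
}

#' Fit a Gaussian mixture by EM
#'
#' Expectation-maximization with unequal component variances and multiple
#' starts: a quantile-split start plus seeded random perturbations, each
#' advanced a short burn-in, with the best start then run to convergence
#' (log-likelihood improvement below `tol`). Components are relabelled by
#' ascending mean, so `comp-1` is always the low-CpG component.
#'
#' @param x Numeric vector of at least `10 * k` finite values.
#' @param k Number of components (1 or 2); k = 1 delegates to
#'   [fit_single_gaussian()].
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations for the final run.
#' @param n_starts Number of starting points.
#' @param seed Optional integer seed fixing the random starts.
#' @param sigma_floor Lower bound on component standard deviations,
#'   preventing variance collapse.
#' @return A `cpg_mixfit`; its `loglik_trace` element records the final
#'   run's log-likelihood path (non-decreasing by construction of EM).
#' @export
fit_mixture_em <- function(x, k = 2L, tol = 1e-8, max_iter = 2000L,
                           n_starts = 10L, seed = NULL,
                           sigma_floor = 1e-4) {
  if (anyNA(x) || any(!is.finite(x))) stop("x contains non-finite values")
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2")
  if (length(x) < 10L * k)
    stop("insufficient data: need at least ", 10L * k, " values")
  if (k == 1L) return(fit_single_gaussian(x, sigma_floor))
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)

  starts <- vector("list", n_starts)
  starts[[1L]] <- em_start(x, 0.5)
  if (n_starts > 1L) {
    qs <- runif(n_starts - 1L, 0.2, 0.8)
    for (i in seq_len(n_starts - 1L)) {
      s <- em_start(x, qs[i])
      s$mu <- s$mu + rnorm(2L, 0, 0.25 * sd(x))
      starts[[i + 1L]] <- s
    }
  }
  # short burn-in on every start, full run from the best
  burn <- lapply(starts, function(s)
    em_iterate(x, s$lambda, s$mu, s$sigma, tol = tol * 100,
               max_iter = 100L, sigma_floor = sigma_floor))
  lls <- vapply(burn, `[[`, 0, "loglik")
  if (all(!is.finite(lls))) stop("EM failed: no start reached a finite log-likelihood")
  best <- burn[[which.max(lls)]]
  fit <- em_iterate(x, best$lambda, best$mu, best$sigma, tol = tol,
                    max_iter = max_iter, sigma_floor = sigma_floor,
                    trace = TRUE)
  if (!fit$converged)
    warning("EM did not reach tolerance ", tol, " within ", max_iter,
            " iterations; returning best partial fit")
  bic <- -2 * fit$loglik + n_mix_params(2L) * log(n)
  new_mixfit(2L, fit$lambda, fit$mu, fit$sigma, fit$loglik, bic, n,
             fit$converged, fit$n_iter, fit$loglik_trace)
}

#' Compare single-Gaussian and mixture fits
#'
#' Reports both the raw log-likelihood comparison and the Bayesian
#' information criterion; selection is by lower BIC.
#'
#' @param fit1,fit2 `cpg_mixfit` objects fitted to the same data.
#' @return A list with `loglik_k1`, `loglik_k2`, `bic_k1`, `bic_k2`,
#'   `delta_bic` (k2 minus k1) and `selected_k`.
#' @export
select_model <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "cpg_mixfit"), inherits(fit2, "cpg_mixfit"))
  if (fit1$n != fit2$n)
    stop("fits are not on the same data (n = ", fit1$n, " vs ", fit2$n, ")")
  if (fit1$k != 1L || fit2$k != 2L)
    stop("expected fit1 with k = 1 and fit2 with k = 2")
  list(loglik_k1 = fit1$loglik, loglik_k2 = fit2$loglik,
       bic_k1 = fit1$bic, bic_k2 = fit2$bic,
       delta_bic = fit2$bic - fit1$bic,
       selected_k = if (fit2$bic < fit1$bic) 2L else 1L)
}

#' Intersection of the two weighted component densities
#'
#' Solves `lambda1 * N(x | mu1, sigma1) = lambda2 * N(x | mu2, sigma2)`
#' analytically (after taking logs the equation is quadratic in x, or linear
#' when the two standard deviations are equal). With unequal variances the
#' equation has two roots; the one separating the component bulks — the root
#' closest to the interval `[mu1, mu2]`, which is the in-interval root
#' whenever one exists — is returned. With strongly unbalanced mixing
#' proportions this crossing can fall slightly outside `(mu1, mu2)`.
#'
#' @param fit A `cpg_mixfit` with k = 2 (components ordered by mean).
#' @return The intersection threshold (scalar).
#' @export
component_intersection <- function(fit) {
  stopifnot(inherits(fit, "cpg_mixfit"))
  if (fit$k != 2L) stop("component_intersection requires a 2-component fit")
  l1 <- fit$lambda[1L]; l2 <- fit$lambda[2L]
  m1 <- fit$mu[1L]; m2 <- fit$mu[2L]
  s1 <- fit$sigma[1L]; s2 <- fit$sigma[2L]
  if (!(m1 < m2)) stop("component means must be distinct and ordered")
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((l1 * s2) / (l2 * s1))
  if (abs(a) < 1e-12) {
    # equal variances: the log-density difference is linear in x
    if (abs(b) < 1e-300) stop("densities never intersect")
    return(-cc / b)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0)
    stop("component densities have no real intersection; ",
         "consider a quantile-based fallback threshold")
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  dist_to_interval <- function(r) pmax(0, pmax(m1 - r, r - m2))
  roots[which.min(dist_to_interval(roots))]
}

#' Classify genes into low- and high-CpG components
#'
#' Genes with `cpg_oe < threshold` are assigned to the low-CpG component
#' (predicted hypermethylated); genes at or above the threshold to the
#' high-CpG component. The fraction of CpG-depleted genes (`cpg_oe < 1`) is
#' reported alongside.
#'
#' @param records CpG profile data.frame (needs `gene_id` and `cpg_oe`), as
#'   returned by [profile_transcriptome()].
#' @param threshold Finite classification threshold, typically from
#'   [component_intersection()].
#' @return An object of class `cpg_split`: list with `threshold`, `genes`
#'   (data.frame `gene_id`, `cpg_oe`, `component`), `n_low`, `n_high` and
#'   `frac_depleted`.
#' @export
classify_genes <- function(records, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (nrow(records) == 0L) stop("no genes to classify")
  comp <- ifelse(records$cpg_oe < threshold, "low", "high")
  genes <- data.frame(gene_id = records$gene_id, cpg_oe = records$cpg_oe,
                      component = comp, stringsAsFactors = FALSE)
  structure(
    list(threshold = threshold, genes = genes,
         n_low = sum(comp == "low"), n_high = sum(comp == "high"),
         frac_depleted = mean(records$cpg_oe < 1)),
    class = "cpg_split")
}

#' @export
print.cpg_split <- function(x, ...) {
  cat(sprintf(paste0("component split at CpG O/E threshold %.4f: ",
                     "%d low / %d high (%.2f%% CpG-depleted)\n"),
              x$threshold, x$n_low, x$n_high, 100 * x$frac_depleted))
  invisible(x)
}

#' Write a mixture report TSV (per-component parameters + model comparison)
#'
#' @param fit1,fit2 k = 1 and k = 2 fits.
#' @param selection Result of [select_model()].
#' @param threshold Intersection threshold.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mixture_report <- function(fit1, fit2, selection, threshold, path) {
  df <- data.frame(
    component = c("comp-1", "comp-2"),
    lambda = fit2$lambda, mu = fit2$mu, sigma = fit2$sigma,
    loglik_k1 = fit1$loglik, loglik_k2 = fit2$loglik,
    bic_k1 = fit1$bic, bic_k2 = fit2$bic,
    selected_k = selection$selected_k,
    threshold = threshold,
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}
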