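#' @title Statistical primitives
#'
#' @description
#' Self-contained implementations of the small set of tests the pipeline
#' relies on: Fisher's exact test for 2x2 tables, Benjamini-Hochberg FDR,
#' Pearson/Spearman correlation, Welch's t-test, one-way ANOVA and ordinary
#' least squares. All tests are two-sided.
#'
#' @name stats-core
NULL

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities (margins
#' fixed) of all tables at most as probable as the observed one, with a
#' small relative slack (1e-7) absorbing floating-point ties. The odds
#' ratio is the sample odds ratio `(a*d)/(b*c)` (`Inf` when only the
#' denominator is zero, `NaN` when both are). A table with any zero margin
#' carries no information: `p = 1` and `zero_margin = TRUE`.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#' @return List with `odds_ratio`, `p_value`, `zero_margin`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  or <- (a * d) / (b * c)  # 0/0 -> NaN, x/0 -> Inf by IEEE convention
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0L || n2 == 0L || k == 0L || (b + d) == 0L)
    return(list(odds_ratio = or, p_value = 1, zero_margin = TRUE))
  support <- max(0L, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  p_obs <- logp[support == a]
  p <- sum(exp(logp[logp <= p_obs + log1p(1e-7)]))
  list(odds_ratio = or, p_value = min(1, p), zero_margin = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: with p-values sorted ascending,
#' `q_i = min_{j >= i} (p_j * m / j)` capped at 1, returned in the input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[ro]
}

#' Correlation test (Pearson or Spearman)
#'
#' Pearson's r with a t-distribution p-value (df = n - 2); Spearman's rho
#' is Pearson on average-tied ranks, with the same t approximation.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite,
#'   non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate`, `statistic` (t), `p_value`, `n`, `method`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(estimate = r, statistic = tstat, p_value = p, n = n, method = method)
}

#' Two-sample t-test (Welch by default)
#'
#' Welch's statistic with Satterthwaite degrees of freedom; set
#' `pooled = TRUE` for the equal-variance version. Two identical
#' zero-variance samples give `t = 0, p = 1` rather than 0/0.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param pooled Use the pooled-variance statistic instead of Welch.
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`, `n`.
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite")
  v1 <- var(x); v2 <- var(y)
  delta <- mean(x) - mean(y)
  if (v1 + v2 == 0) {
    # exact-equality branch for degenerate zero-variance samples
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    return(list(statistic = stat, df = n1 + n2 - 2,
                p_value = if (delta == 0) 1 else 0,
                mean_x = mean(x), mean_y = mean(y), n = c(n1, n2)))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- delta / se
  list(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df),
       mean_x = mean(x), mean_y = mean(y), n = c(n1, n2))
}

#' One-way analysis of variance
#'
#' @param groups List of >= 2 numeric samples, each of size >= 2.
#' @return List with `statistic` (F), `df_between`, `df_within`, `p_value`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  all_x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(all_x))) stop("groups must be finite")
  grand <- mean(all_x)
  ssb <- sum(sizes * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1L
  dfw <- length(all_x) - length(groups)
  if (ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / dfb) / (ssw / dfw)
    p <- pf(f, dfb, dfw, lower.tail = FALSE)
  }
  list(statistic = f, df_between = dfb, df_within = dfw, p_value = p)
}

#' Ordinary least squares line
#'
#' @param x,y Numeric vectors (n >= 3); `x` must not be constant.
#' @return List with `slope`, `intercept`, `r_squared` (`NA` for constant
#'   `y`, where explained variance is undefined).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant; slope undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else
    1 - sum((y - intercept - slope * x)^2) / sst
  list(slope = slope, intercept = intercept, r_squared = r2)
}
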