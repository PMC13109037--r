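#' Boxplot (Tukey fence) outlier inclusion mask
#'
#' Keeps values inside [Q1 - 1.5 IQR, Q3 + 1.5 IQR], with quartiles by linear
#' interpolation (type-7 quantiles). NA values are excluded.
#'
#' @param values numeric vector (>= 4 non-missing values).
#' @return logical inclusion mask, same length as `values`.
#' @export
boxplot_outlier_mask <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4) abort("need at least 4 values to define boxplot fences")
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  ok & values >= lo & values <= hi
}

#' Two-sided Mann-Whitney / Wilcoxon rank-sum test
#'
#' Exact enumeration when both groups have n <= 20 and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' Reports the statistic both as U (pairs where a exceeds b, counting ties as
#' half) and as the rank sum W of the first group.
#'
#' @param a,b numeric vectors (nonempty).
#' @return list: `U`, `W` (rank sum of `a`), `p`.
#' @export
mann_whitney_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("both groups must be nonempty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  U <- W - na * (na + 1) / 2
  if (length(unique(c(a, b))) == 1) {
    warning("all values tied across both groups; p = 1")
    return(list(U = U, W = W, p = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && max(na, nb) <= 20
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = U, W = W, p = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvals numeric vector of raw p-values in [0, 1] (NA passed through).
#' @return adjusted p-values, monotone in raw-p order, capped at 1.
#' @export
bh_fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Cliff's delta with a normal-approximation confidence interval
#'
#' delta = [#(a_i > b_j) - #(a_i < b_j)] / (n_a n_b), positive when the
#' first group is stochastically larger. The CI uses Cliff's consistent
#' unbiased variance estimator with a normal critical value, truncated to
#' [-1, 1]; degenerate at complete separation (variance 0).
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @param conf confidence level (default 0.95).
#' @return list: `delta`, `ci_low`, `ci_high`.
#' @export
cliffs_delta <- function(a, b, conf = 0.95) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("both groups need >= 2 values")
  d <- sign(outer(a, b, "-"))            # n_a x n_b dominance matrix
  delta <- mean(d)
  di <- rowMeans(d)
  dj <- colMeans(d)
  s2 <- (nb^2 * sum((di - delta)^2) + na^2 * sum((dj - delta)^2) -
           sum((d - delta)^2)) / (na * nb * (na - 1) * (nb - 1))
  s2 <- max(s2, 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(delta = delta,
       ci_low = max(-1, delta - z * sqrt(s2)),
       ci_high = min(1, delta + z * sqrt(s2)))
}

#' ANCOVA: group effect adjusted for age
#'
#' Fits y ~ group + age by least squares and tests the group term with a
#' type-III (equivalently, for this two-term model, nested-model) F test.
#' Also returns covariate-adjusted group means at the overall mean age.
#'
#' @param y numeric response.
#' @param group two-level factor or character vector.
#' @param age numeric covariate.
#' @return list: `F_group`, `p_group`, `adjusted_means` (named by group).
#' @export
ancova_group_age <- function(y, group, age) {
  ok <- stats::complete.cases(y, group, age)
  y <- y[ok]; group <- factor(group[ok]); age <- age[ok]
  if (nlevels(group) != 2) abort("group must have exactly two levels")
  if (min(table(group)) < 3) abort("need >= 3 subjects per group")
  if (stats::sd(age) == 0) abort("age does not vary; design is collinear")
  if (stats::sd(y) == 0) {
    adj <- stats::setNames(rep(y[1], 2), levels(group))
    return(list(F_group = 0, p_group = 1, adjusted_means = adj))
  }
  fit1 <- stats::lm(y ~ group + age)
  if (any(!is.finite(stats::coef(fit1)))) abort("collinear design")
  fit0 <- stats::lm(y ~ age)
  an <- stats::anova(fit0, fit1)
  F_group <- an$F[2]
  p_group <- an$`Pr(>F)`[2]
  if (!is.finite(F_group)) { F_group <- 0; p_group <- 1 }  # zero-variance response
  beta <- stats::coef(fit1)
  mean_age <- mean(age)
  adj <- c(beta[1] + beta[3] * mean_age,
           beta[1] + beta[2] + beta[3] * mean_age)
  names(adj) <- levels(group)
  list(F_group = F_group, p_group = p_group, adjusted_means = adj)
}

#' Tied ranks (average rank for ties)
#'
#' Ascending ranks 1..n; tied values share the average of their rank span.
#'
#' @param values finite numeric vector.
#' @return numeric rank vector summing to n(n+1)/2.
#' @export
tiedrank <- function(values) {
  if (!all(is.finite(values))) abort("values must be finite")
  rank(values, ties.method = "average")
}

#' Partial Spearman correlation
#'
#' Rank-transforms x, y and each covariate (average ranks for ties),
#' residualizes ranked x and ranked y on the ranked covariates (with
#' intercept) by least squares, and correlates the residuals. The p-value
#' uses the t approximation with n - 2 - (number of covariates) degrees of
#' freedom. With no covariates this is exactly Spearman's rho.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariate columns, or NULL.
#' @return list: `rho`, `p`, `df`, `covariates` (names).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  cov_mat <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  ok <- stats::complete.cases(x, y, if (is.null(cov_mat)) rep(TRUE, length(x)) else cov_mat)
  x <- x[ok]; y <- y[ok]
  if (!is.null(cov_mat)) cov_mat <- cov_mat[ok, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(cov_mat)) 0L else ncol(cov_mat)
  if (n <= k + 2) abort("need n > number of covariates + 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant x or y")
  rx <- tiedrank(x); ry <- tiedrank(y)
  if (k > 0) {
    rc <- apply(cov_mat, 2, tiedrank)
    X <- cbind(1, rc)
    rx <- stats::lsfit(X, rx, intercept = FALSE)$residuals
    ry <- stats::lsfit(X, ry, intercept = FALSE)$residuals
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(rho = rho, p = p, df = df,
       covariates = if (k > 0) colnames(cov_mat) else character(0))
}

#' Group comparison table with rank-sum tests, FDR and Cliff's delta
#'
#' For each variable: optional per-group boxplot outlier removal, two-sided
#' Mann-Whitney test, group medians and IQRs, Cliff's delta with 95% CI.
#' Benjamini-Hochberg adjustment is applied within the variable family given
#' (all variables passed in one call form one family).
#'
#' @param values data.frame of numeric variables (one column per variable,
#'   one row per subject).
#' @param group two-level vector aligned with rows of `values`; the first
#'   level (alphabetical, or factor level order) is the reference group `a`
#'   in delta = delta(a, b).
#' @param remove_outliers logical: apply per-group boxplot outlier removal
#'   before testing (used for metabolites, not network metrics).
#' @param family label recorded in the output (multiplicity family name).
#' @return data.frame of class `idscn_comparison`, one row per variable:
#'   variable, family, median/IQR and n per group, U, W, delta, ci_low,
#'   ci_high, p, p_adj.
#' @export
compare_groups_table <- function(values, group, remove_outliers = FALSE,
                                 family = "default") {
  stopifnot(is.data.frame(values))
  group <- factor(group)
  if (nlevels(group) != 2) abort("group must have exactly two levels")
  lev <- levels(group)
  rows <- lapply(names(values), function(v) {
    xa <- values[[v]][group == lev[1]]
    xb <- values[[v]][group == lev[2]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (remove_outliers) {
      xa <- xa[boxplot_outlier_mask(xa)]
      xb <- xb[boxplot_outlier_mask(xb)]
    }
    mw <- suppressWarnings(mann_whitney_test(xa, xb))
    cd <- cliffs_delta(xa, xb)
    data.frame(
      variable = v, family = family,
      median_a = stats::median(xa), iqr_a = stats::IQR(xa, type = 7),
      median_b = stats::median(xb), iqr_b = stats::IQR(xb, type = 7),
      n_a = length(xa), n_b = length(xb),
      U = mw$U, W = mw$W,
      delta = cd$delta, ci_low = cd$ci_low, ci_high = cd$ci_high,
      p = mw$p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr_adjust(out$p)
  attr(out, "group_levels") <- lev
  class(out) <- c("idscn_comparison", class(out))
  out
}
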