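test_that("boxplot fences exclude extremes and keep clean data", {
  expect_equal(boxplot_outlier_mask(c(1, 2, 3, 4, 100)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(boxplot_outlier_mask(rep(7, 6))))          # IQR 0, closed interval
  expect_true(all(boxplot_outlier_mask(c(-2, -1, 0, 1, 2))))
  expect_error(boxplot_outlier_mask(c(1, 2, 3)), "at least 4")
})

test_that("Mann-Whitney statistics and p-values match exact enumeration", {
  mw <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$W, 6)       # ranks 1+2+3
  expect_equal(mw$p, 0.1, tolerance = 1e-12)   # 2 * 1/choose(6,3)
  # identical samples: exchangeable, p = 1
  expect_equal(suppressWarnings(mann_whitney_test(c(1, 2, 3), c(1, 2, 3))$p), 1)
  expect_warning(out <- mann_whitney_test(c(2, 2), c(2, 2)), "tied")
  expect_equal(out$p, 1)
  # U + U' identity and W consistency on random data
  set.seed(211)
  a <- rnorm(12); b <- rnorm(9)
  mw2 <- mann_whitney_test(a, b)
  mw2r <- mann_whitney_test(b, a)
  expect_equal(mw2$U + mw2r$U, 12 * 9)
  expect_equal(mw2$W, sum(rank(c(a, b))[1:12]))
})

test_that("Mann-Whitney agrees with a permutation oracle on small samples", {
  set.seed(223)
  a <- rnorm(6); b <- rnorm(5) + 0.8
  p_obs <- mann_whitney_test(a, b)$p
  pool <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u0 <- u_stat(a, b)
  dev0 <- abs(u0 - length(a) * length(b) / 2)
  combs <- utils::combn(11, 6)
  devs <- apply(combs, 2, function(idx)
    abs(u_stat(pool[idx], pool[-idx]) - 15))
  p_exact <- mean(devs >= dev0 - 1e-12)
  expect_equal(p_obs, p_exact, tolerance = 1e-10)
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(bh_fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr_adjust(0.73), 0.73)
  p <- c(0.003, 0.04, 0.2, 0.9, 0.012)
  # hand computation: sort, p * m / i, cumulative min from the top, cap at 1
  ord <- order(p)
  hand <- pmin(1, rev(cummin(rev(p[ord] * 5 / seq_len(5)))))[order(ord)]
  expect_equal(bh_fdr_adjust(p), hand, tolerance = 1e-12)
  expect_true(all(bh_fdr_adjust(p) >= p))
  expect_error(bh_fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Cliff's delta equals pair counting, with valid CI and antisymmetry", {
  expect_equal(cliffs_delta(c(4, 5, 6), c(1, 2, 3))$delta, 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3))$delta, 0)
  set.seed(227)
  for (i in 1:10) {
    a <- sample(1:8, 9, replace = TRUE)   # ties on purpose
    b <- sample(1:8, 7, replace = TRUE) + runif(1, -1, 1)
    cd <- cliffs_delta(a, b)
    bf <- bf_cliffs_delta(a, b)
    expect_equal(cd$delta, bf$delta, tolerance = 1e-12)
    # dominance-probability identity delta = 2 P(a>b) + P(a=b) - 1
    expect_equal(cd$delta, 2 * bf$p_gt + bf$p_eq - 1, tolerance = 1e-12)
    expect_equal(cliffs_delta(b, a)$delta, -cd$delta, tolerance = 1e-12)
    expect_true(cd$ci_low >= -1 && cd$ci_high <= 1)
    expect_true(cd$ci_low <= cd$delta && cd$delta <= cd$ci_high)
  }
})

test_that("ANCOVA group test matches hand-solved normal equations", {
  # 6 subjects, age orthogonal to group, strong group shift
  y <- c(10, 11, 12, 20, 21, 22)
  g <- rep(c("A", "B"), each = 3)
  age <- c(30, 40, 50, 30, 40, 50)
  out <- ancova_group_age(y, g, age)
  # closed form: with orthogonal design, group SS = n/2 * (mean_B - mean_A)^2 / 2...
  fit <- stats::lm(y ~ factor(g) + age)
  an <- stats::anova(stats::lm(y ~ age), fit)
  expect_equal(out$F_group, an$F[2], tolerance = 1e-9)
  expect_equal(out$p_group, an$`Pr(>F)`[2], tolerance = 1e-9)
  expect_lt(out$p_group, 1e-6)
  expect_equal(unname(out$adjusted_means), c(11, 21), tolerance = 1e-9)
  # degenerate constant response
  out0 <- ancova_group_age(rep(5, 6), g, age)
  expect_equal(out0$F_group, 0)
  expect_equal(out0$p_group, 1)
  expect_error(ancova_group_age(y, g, rep(40, 6)), "collinear|vary")
})

test_that("ANCOVA p-values are roughly uniform under label permutation", {
  set.seed(229)
  y <- rnorm(40); age <- runif(40, 20, 60)
  ps <- replicate(200, {
    g <- sample(rep(c("A", "B"), 20))
    ancova_group_age(y, g, age)$p_group
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("tiedrank averages tie spans and conserves rank sums", {
  expect_equal(tiedrank(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
  expect_equal(tiedrank(1:7), as.numeric(1:7))
  set.seed(233)
  for (i in 1:5) {
    v <- sample(1:5, 12, replace = TRUE)
    expect_equal(sum(tiedrank(v)), 12 * 13 / 2)
  }
  expect_error(tiedrank(c(1, Inf)), "finite")
})

test_that("partial Spearman reduces to Spearman and removes confounders", {
  set.seed(239)
  x <- rnorm(30); y <- rnorm(30)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(ps$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  # monotone relation: rho near 1 at moderate n
  x2 <- rnorm(200)
  ps2 <- partial_spearman(x2, exp(x2) + rnorm(200, 0, 0.01),
                          covariates = data.frame(c1 = rnorm(200)))
  expect_gt(ps2$rho, 0.95)
  # shared confounder is removed
  z <- rnorm(300)
  ps3 <- partial_spearman(z + rnorm(300, 0, 0.2), z + rnorm(300, 0, 0.2),
                          covariates = data.frame(z = z))
  expect_lt(abs(ps3$rho), 0.15)
  expect_error(partial_spearman(rep(1, 10), rnorm(10)), "constant")
})

test_that("rank-based decisions are invariant to monotone transforms", {
  set.seed(241)
  a <- rlnorm(15); b <- rlnorm(18) * 1.5
  p1 <- mann_whitney_test(a, b)$p
  p2 <- mann_whitney_test(log(a), log(b))$p
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(cliffs_delta(a, b)$delta, cliffs_delta(sqrt(a), sqrt(b))$delta,
               tolerance = 1e-12)
})

test_that("group comparison table wires outlier removal, tests and FDR together", {
  set.seed(251)
  n <- 30
  vals <- data.frame(v1 = c(rnorm(n, 10), rnorm(n, 12)),
                     v2 = rnorm(2 * n),
                     v3 = rnorm(2 * n))
  group <- rep(c("HC", "SM"), each = n)
  tab <- compare_groups_table(vals, group, family = "demo")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_adj >= tab$p))
  expect_lt(tab$delta[tab$variable == "v1"], 0)       # HC < SM shift
  expect_lt(tab$p_adj[tab$variable == "v1"], 0.05)
  # an extreme value appended to one group is excluded by the outlier stage,
  # leaving the test result unchanged
  t_clean <- compare_groups_table(vals["v1"], group, remove_outliers = TRUE)
  vals2 <- data.frame(v1 = c(vals$v1, 1e4))
  group2 <- c(group, "HC")
  t_dirty <- compare_groups_table(vals2, group2, remove_outliers = TRUE)
  expect_equal(t_dirty$p, t_clean$p, tolerance = 1e-12)
  expect_equal(t_dirty$n_a, t_clean$n_a)
  expect_equal(t_dirty$delta, t_clean$delta, tolerance = 1e-12)
})
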