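test_that("exact linear fit has zero robust standard error", {
  x <- 1:20
  y <- 3 + 2 * x
  cl <- rep(1:5, each = 4)
  fit <- ols_cluster_robust(y, cbind(1, x = x), cl)
  expect_equal(fit$coefficients$estimate, c(3, 2))
  expect_equal(fit$coefficients$se, c(0, 0))
})

test_that("singleton clusters reduce to HC1 heteroskedasticity-robust", {
  set.seed(10)
  n <- 40
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n, sd = abs(x) + 0.2)
  X <- cbind(1, x = x)
  fit <- ols_cluster_robust(y, X, seq_len(n))
  # direct HC1 computation: N/(N-k) * bread' meat bread
  u <- y - X %*% qr.solve(X, y)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * as.vector(u))
  hc1 <- (n / (n - 2)) * bread %*% meat %*% bread
  expect_equal(unname(fit$vcov), unname(hc1), tolerance = 1e-10)
})

test_that("clustered covariance matches the sandwich package oracle", {
  skip_if_not_installed("sandwich")
  set.seed(11)
  n <- 60
  cl <- rep(1:12, each = 5)
  x <- rnorm(12)[cl] + rnorm(n)
  y <- 2 + 0.3 * x + rnorm(12)[cl] + rnorm(n)
  fit <- ols_cluster_robust(y, cbind(`(Intercept)` = 1, x = x), cl)
  lmf <- lm(y ~ x)
  V <- sandwich::vcovCL(lmf, cluster = cl, type = "HC1", cadjust = TRUE)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-10)
})

test_that("design-matrix problems raise informative errors", {
  x <- rnorm(20)
  X <- cbind(1, x = x, x2 = 2 * x)
  expect_error(ols_cluster_robust(rnorm(20), X, rep(1:5, 4)), "x2")
  expect_error(ols_cluster_robust(rnorm(20), cbind(1, x), rep(1, 20)),
               ">= 2 clusters")
})

test_that("perfectly collinear group recovers r = 1 and the slope", {
  d <- simulate_cohort(cohort_sim_config(seed = 2L))
  d$a_meth_pct[d$group == "CTCT"] <- 5 + 2 * d$pct_a[d$group == "CTCT"]
  res <- cor_meth_analysis(d)
  ct <- res[res$group == "CTCT", ]
  expect_equal(ct$cor, 1)
  expect_equal(ct$slope, 2)
  # zero-variance %A is reported as absent, not an error
  d2 <- simulate_cohort(cohort_sim_config(seed = 3L))
  d2$pct_a[d2$group == "PRPR"] <- 50
  res2 <- cor_meth_analysis(d2)
  expect_true(is.na(res2$cor[res2$group == "PRPR"]))
})

test_that("permutation null keeps the clustered p-value near-uniform", {
  d <- simulate_cohort(cohort_sim_config(seed = 17L))
  g <- d[d$group == "PRCT", ]
  set.seed(99)
  perm_p <- vapply(1:400, function(i) {
    g$a_meth_pct <- sample(g$a_meth_pct)
    fit <- ols_cluster_robust(g$a_meth_pct,
                              cbind(1, pct_a = g$pct_a), g$litter)
    fit$coefficients$p[2]
  }, numeric(1))
  # permuting breaks the %A-methylation link: the p-value distribution
  # should track the uniform at the usual working thresholds
  expect_lt(abs(mean(perm_p < 0.05) - 0.05), 0.04)
  expect_lt(abs(mean(perm_p < 0.5) - 0.5), 0.08)
  expect_gt(min(perm_p), 0)
  expect_lte(max(perm_p), 1)
})

test_that("phenotype model recovers an exact group shift", {
  d <- simulate_cohort(cohort_sim_config(seed = 5L))
  base <- mean(d$death_weight[d$group == "CTCT"])
  d$death_weight[d$group == "CTCT"] <- 30
  d$death_weight[d$group == "CTPR"] <- 30 - 2.48
  fit <- phenotype_lm(d, "death_weight")
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "CTPR"], -2.48)
  expect_equal(co$se[co$term == "CTPR"], 0)
  # constant phenotype: all contrasts zero
  d$death_weight <- 25
  fit0 <- phenotype_lm(d, "death_weight")
  expect_equal(fit0$coefficients$estimate[-1], c(0, 0, 0))
  expect_error(phenotype_lm(d, "no_such_column"), "not found")
})

test_that("fasting loss arithmetic", {
  expect_equal(fasting_loss(30, 27), 10)
  expect_equal(fasting_loss(25, 25), 0)
  expect_equal(fasting_loss(20, 21), -5)
  expect_error(fasting_loss(0, 1), "> 0")
})

test_that("Welch test on litter means matches the direct formula", {
  v <- c(5.1, 5.1, 4.9, 5.0, 5.2, 3.9, 4.1, 4.0)
  litters <- c("a", "a", "b", "c", "d", "e", "f", "g")
  groups <- c("G1", "G1", "G1", "G1", "G1", "G2", "G2", "G2")
  res <- welch_on_litter_means(v, litters, groups)
  m1 <- c(5.1, 4.9, 5.0, 5.2); m2 <- c(3.9, 4.1, 4.0)
  se2 <- var(m1) / 4 + var(m2) / 3
  t_hand <- (mean(m1) - mean(m2)) / sqrt(se2)
  df_hand <- se2^2 / ((var(m1) / 4)^2 / 3 + (var(m2) / 3)^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand))
  # identical litter-mean sets: t = 0, p = 1
  same <- welch_on_litter_means(c(1, 2, 3, 1, 2, 3),
                                c("a", "b", "c", "d", "e", "f"),
                                rep(c("G1", "G2"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate zero variance with separated means: flagged limit
  expect_warning(
    deg <- welch_on_litter_means(c(10, 10, 10, 20, 20, 20),
                                 c("a", "b", "c", "d", "e", "f"),
                                 rep(c("G1", "G2"), each = 3)),
    "zero variance")
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  # a litter spanning groups is an error
  expect_error(welch_on_litter_means(1:4, c("a", "a", "b", "b"),
                                     c("G1", "G2", "G2", "G2")),
               "spanning")
})

test_that("one-way ANOVA reduces to the squared pooled t for two groups", {
  set.seed(12)
  v <- c(rnorm(8, 5), rnorm(9, 6))
  g <- rep(c("A", "B"), c(8, 9))
  res <- one_way_anova(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # identical groups: F = 0, p = 1
  res0 <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("A", "B", "C"), each = 3))
  expect_equal(res0$p, 1)
  # constant response is not an error
  resc <- one_way_anova(rep(4, 9), rep(c("A", "B", "C"), each = 3))
  expect_equal(resc$F, 0)
  expect_equal(resc$p, 1)
  # clear separation
  ress <- one_way_anova(c(rnorm(5, 0, 0.1), rnorm(5, 100, 0.1)),
                        rep(c("A", "B"), each = 5))
  expect_lt(ress$p, 1e-6)
})

test_that("Fisher exact test matches enumeration oracles on small tables", {
  t1 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact_rxc(t1)$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(t1)$p, oracle_fisher_2x2(t1),
               tolerance = 1e-12)
  t2 <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact_rxc(t2)$p, oracle_fisher_2x2(t2),
               tolerance = 1e-12)
  t3 <- matrix(c(5, 3, 2, 1, 4, 6), 2)
  expect_equal(fisher_exact_rxc(t3)$p, oracle_fisher_2x3(t3),
               tolerance = 1e-12)
  # proportional rows are the null mode: p = 1
  expect_equal(fisher_exact_rxc(matrix(c(10, 5, 10, 5), 2))$p, 1)
  expect_equal(fisher_exact_rxc(matrix(c(6, 3, 4, 2, 2, 1), 2))$p, 1)
  # input validation
  expect_error(fisher_exact_rxc(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 1, 1), 2)), "margin")
})

test_that("large tables route to the network algorithm consistently", {
  set.seed(3)
  tab <- matrix(rpois(22, 20) + 1L, nrow = 2)
  res <- fisher_exact_rxc(tab)
  expect_equal(res$method, "network")
  expect_equal(res$p, fisher.test(tab, workspace = 2e8)$p.value,
               tolerance = 1e-12)
  # Monte-Carlo fallback is seeded and reports its standard error
  big <- matrix(rpois(12, 200) + 1L, nrow = 2)
  r1 <- fisher_exact_rxc(big, seed = 5L)
  r2 <- fisher_exact_rxc(big, seed = 5L)
  expect_equal(r1$method, "montecarlo")
  expect_identical(r1$p, r2$p)
  expect_true(is.finite(r1$mc_se))
})

test_that("Bonferroni adjustment is capped, monotone and idempotent", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.4, 3), 1)
  expect_equal(bonferroni(0, 10), 0)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(bonferroni(p, 3)) >= 0))
  expect_equal(bonferroni(bonferroni(p, 3), 1), bonferroni(p, 3))
  expect_error(bonferroni(1.2, 2), "p")
})
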