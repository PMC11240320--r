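test_that("the normality gate routes to t or Wilcoxon", {
  set.seed(1)
  g <- two_group_test(rnorm(25), rnorm(25, 1))
  expect_identical(g$test_used, "t")
  expect_lt(g$p_value, 0.05)
  set.seed(2)
  h <- two_group_test(rcauchy(25), rcauchy(25))
  expect_identical(h$test_used, "wilcoxon")
  # elementwise-identical paired samples: null identity
  x <- rnorm(10)
  idem <- two_group_test(x, x, paired = TRUE)
  expect_identical(idem$p_value, 1)
  expect_error(two_group_test(rnorm(2), rnorm(5)), "n >= 3")
})

test_that("the balanced LMM p-value equals the paired t-test", {
  set.seed(3)
  for (rep in 1:5) {
    n_pat <- 12
    a <- rnorm(n_pat); b <- a + 0.5 + rnorm(n_pat, 0, 0.7)
    long <- data.frame(value = c(a, b),
                       condition = rep(c("a", "b"), each = n_pat),
                       patient = rep(seq_len(n_pat), 2))
    lmm <- lmm_random_intercept(long, "value", "condition", "patient")
    tt <- t.test(b, a, paired = TRUE)
    expect_equal(lmm$p_value, tt$p.value, tolerance = 1e-6)
    expect_equal(abs(lmm$estimate), abs(unname(tt$estimate)),
                 tolerance = 1e-6)
  }
})

test_that("LMM effect is zero when conditions are identical within patient", {
  long <- data.frame(value = rep(rnorm(8), 2),
                     condition = rep(c("a", "b"), each = 8),
                     patient = rep(1:8, 2))
  # zero residual variance: convergence chatter is expected on this
  # degenerate input, the point estimate is still exact
  fit <- suppressWarnings(
    lmm_random_intercept(long, "value", "condition", "patient"))
  expect_equal(fit$estimate, 0, tolerance = 1e-8)
  long$condition <- "a"
  expect_error(lmm_random_intercept(long, "value", "condition", "patient"),
               "constant")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone on sorted input; permutation-invariant after order restoration
  p <- sort(runif(20))
  expect_false(is.unsorted(bh_fdr(p)))
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$estimate, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$estimate, -1)
  # hand-ranked oracle with average ranks on ties:
  # rank(x) = 1, 2.5, 2.5, 4; rank(y) = 1, 3, 2, 4
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_cor(x, y)$estimate, rho_hand, tolerance = 1e-12)
  expect_error(spearman_cor(c(1, 1, 1, 1), 1:4), "constant")
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
})

test_that("ANOVA + Tukey HSD behaves at the null and under separation", {
  set.seed(5)
  null_vals <- rnorm(60)
  null_groups <- rep(c("a", "b", "c"), 20)
  res <- anova_tukey(null_vals, null_groups)
  expect_gt(res$anova$p_value, 0.01)
  expect_true(all(res$pairwise$p_adj > 0.01))

  sep_vals <- c(rnorm(20), rnorm(20), rnorm(20, 10))
  sep_groups <- rep(c("a", "b", "c"), each = 20)
  res2 <- anova_tukey(sep_vals, sep_groups)
  expect_lt(res2$pairwise$p_adj[res2$pairwise$contrast == "c-a"], 0.05)
  # antisymmetry: relabeling the groups flips the difference's sign
  relab <- c(a = "c", b = "b", c = "a")[sep_groups]
  res3 <- anova_tukey(sep_vals, relab)
  expect_equal(res3$pairwise$estimate[res3$pairwise$contrast == "c-a"],
               -res2$pairwise$estimate[res2$pairwise$contrast == "c-a"],
               tolerance = 1e-10)
  expect_error(anova_tukey(rnorm(4), c("a", "a", "b", "b")), ">= 3 groups")
  expect_error(anova_tukey(rnorm(5), c("a", "a", "b", "b", "c")), "n >= 2")
})

test_that("contingency tests gate on expected counts", {
  balanced <- matrix(c(20, 20, 20, 20), 2)
  res <- contingency_test(balanced)
  expect_identical(res$test_used, "chisq")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  small <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)  # min expected 4.5 < 5
  res2 <- contingency_test(small)
  expect_identical(res2$test_used, "fisher")
  # exact two-sided p by hypergeometric enumeration: with margins fixed,
  # cell (1,1) ~ Hyper(m = 9, n = 11, k = 10); sum the probabilities of all
  # tables at most as likely as the observed one
  dens <- dhyper(0:9, 9, 11, 10)
  p_hyper <- sum(dens[dens <= dhyper(8, 9, 11, 10) * (1 + 1e-7)])
  expect_equal(res2$p_value, p_hyper, tolerance = 1e-10)
  # sample odds ratio is invariant to doubling all cells (keeping the
  # doubled table in the exact branch via the configurable gate)
  expect_equal(contingency_test(small)$estimate,
               contingency_test(2 * small, expected_min = 10)$estimate)
  expect_error(contingency_test(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})
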