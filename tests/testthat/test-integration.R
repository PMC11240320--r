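test_that("block datasets enforce completeness and a two-class outcome", {
  d <- make_shift_blocks(n = 12, p = 6, seed = 1)
  expect_s3_class(block_dataset(d$blocks, d$outcome), "block_dataset")
  bad <- d$blocks; bad$b1[1, 1] <- NA
  expect_error(block_dataset(bad, d$outcome), "complete cases")
  expect_error(block_dataset(d$blocks, rep("a", 12)), "two classes")
  expect_error(block_dataset(unname(d$blocks), d$outcome), "named")
})

test_that("keepX = all features leaves no zero loadings; sparsity hits keepX", {
  d <- make_shift_blocks(n = 20, p = 8, seed = 2)
  bd <- block_dataset(d$blocks, d$outcome)
  full <- fit_block_splsda(bd, integration_config(ncomp = 2))
  expect_true(all(full$loadings$b1 != 0))
  expect_true(all(full$loadings$b2 != 0))
  sparse <- fit_block_splsda(bd, integration_config(
    ncomp = 2, keepX = list(b1 = 3, b2 = 5)))
  expect_identical(colSums(sparse$loadings$b1 != 0), c(3, 3))
  expect_identical(colSums(sparse$loadings$b2 != 0), c(5, 5))
  # unit-norm loadings, canonical sign
  for (h in 1:2) {
    expect_equal(sum(sparse$loadings$b1[, h]^2), 1, tolerance = 1e-10)
    a <- sparse$loadings$b1[, h]
    expect_gt(a[which.max(abs(a))], 0)
  }
})

test_that("the single-block model reduces to sparse PLS-DA", {
  set.seed(3)
  d <- make_shift_blocks(n = 30, p = 12, n_informative = 3, shift = 1.5,
                         block_names = "x", seed = 3)
  bd <- block_dataset(d$blocks, d$outcome)
  m <- fit_block_splsda(bd, integration_config(ncomp = 2,
                                               keepX = list(x = 5)))
  oracle <- oracle_splsda_scores(d$blocks$x, d$outcome, ncomp = 2, keep = 5)
  expect_lt(max(abs(m$scores$x - oracle)), 1e-8)
})

test_that("successive per-block scores are orthogonal", {
  d <- make_shift_blocks(n = 24, p = 15, seed = 4)
  m <- fit_block_splsda(block_dataset(d$blocks, d$outcome),
                        integration_config(ncomp = 3))
  for (b in names(d$blocks)) {
    g <- crossprod(m$scores[[b]])
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  }
})

test_that("zero cross-block design weight decouples the blocks", {
  d <- make_shift_blocks(n = 26, p = 10, seed = 5)
  joint <- fit_block_splsda(
    block_dataset(d$blocks, d$outcome),
    integration_config(ncomp = 2, design_weight = 0,
                       keepX = list(b1 = 4, b2 = 6)))
  solo1 <- fit_block_splsda(
    block_dataset(d$blocks["b1"], d$outcome),
    integration_config(ncomp = 2, keepX = list(b1 = 4)))
  solo2 <- fit_block_splsda(
    block_dataset(d$blocks["b2"], d$outcome),
    integration_config(ncomp = 2, keepX = list(b2 = 6)))
  expect_equal(joint$loadings$b1, solo1$loadings$b1, tolerance = 1e-10)
  expect_equal(joint$loadings$b2, solo2$loadings$b2, tolerance = 1e-10)
})

test_that("planted discriminative features are selected", {
  d <- make_shift_blocks(n = 40, p = 20, n_informative = 5, shift = 2,
                         seed = 6)
  m <- fit_block_splsda(block_dataset(d$blocks, d$outcome),
                        integration_config(ncomp = 1,
                                           keepX = list(b1 = 10, b2 = 10)))
  for (b in c("b1", "b2")) {
    planted <- sprintf("%s_f%03d", b, 1:5)
    expect_true(all(planted %in% m$selected[[b]][[1]]))
  }
  feats <- selected_features(m)
  expect_identical(nrow(feats), 20L)
  expect_true(all(feats$association %in% c(-1L, 1L)))
})

test_that("prediction assigns centroid members and agrees across distances when isotropic", {
  d <- make_shift_blocks(n = 30, p = 10, shift = 3, seed = 7)
  bd <- block_dataset(d$blocks, d$outcome)
  m_cent <- fit_block_splsda(bd, integration_config(
    ncomp = 2, keepX = list(b1 = 5, b2 = 5), distance = "centroid"))
  pr <- predict(m_cent, d$blocks)
  expect_gt(mean(pr$class == d$outcome), 0.95)
  # a pseudo-sample projecting exactly onto a class centroid is assigned it
  hi_centroid <- m_cent$centroids$b1["hi", ]
  expect_identical(
    as.character(predict(m_cent, lapply(d$blocks, function(X) {
      matrix(colMeans(X[d$outcome == "hi", , drop = FALSE]), nrow = 1,
             dimnames = list(NULL, colnames(X)))
    }))$class), "hi")
  # isotropic scores: centroid and Mahalanobis votes coincide
  m_mah <- fit_block_splsda(bd, integration_config(
    ncomp = 2, keepX = list(b1 = 5, b2 = 5), distance = "mahalanobis"))
  pr_mah <- predict(m_mah, d$blocks)
  agreement <- mean(pr_mah$class == pr$class)
  expect_gt(agreement, 0.9)
  expect_error(predict(m_cent, list(b1 = matrix(0, 2, 3),
                                    b2 = d$blocks$b2[1:2, ])),
               "feature names")
})

test_that("tuning returns the only grid point and prefers sparse ties", {
  d <- make_shift_blocks(n = 24, p = 8, shift = 4, seed = 8)
  bd <- block_dataset(d$blocks, d$outcome)
  cfg <- integration_config(ncomp = 1, cv_folds = 3, tune_repeats = 2,
                            seed = 11)
  single <- tune_keepX(bd, cfg, grid = list(b1 = 4, b2 = 4))
  expect_identical(single$keepX, list(b1 = 4L, b2 = 4L))
  # strong signal: every grid point reaches BER 0, ties resolved sparsest
  tuned <- tune_keepX(bd, cfg, grid = list(b1 = c(4, 8), b2 = c(4, 8)))
  expect_true(all(unlist(tuned$keepX) == 4L))
})

test_that("pure-noise tuning yields chance-level error", {
  set.seed(9)
  n <- 24
  y <- factor(rep(c("lo", "hi"), each = n / 2))
  X <- matrix(rnorm(n * 10), n, 10)
  bd <- block_dataset(list(x = X), y)
  cv <- cv_block_splsda(bd, integration_config(ncomp = 1,
                                               keepX = list(x = 5),
                                               cv_folds = 3, seed = 12),
                        repeats = 10)
  expect_gt(cv$ber, 0.25)
  expect_lt(cv$ber, 0.75)
})

test_that("the permutation test reaches its minimal attainable p on strong signal", {
  d <- make_shift_blocks(n = 24, p = 8, shift = 4, seed = 10)
  bd <- block_dataset(d$blocks, d$outcome)
  pt <- permutation_test(bd, integration_config(
    ncomp = 1, keepX = list(b1 = 4, b2 = 4), cv_folds = 3,
    n_permutations = 19, seed = 13))
  expect_equal(pt$p_value, 1 / 20)
  expect_equal(pt$observed_ber, 0)
  expect_gte(pt$p_value, 1 / (19 + 1))
  expect_error(permutation_test(bd, integration_config(n_permutations = 5)),
               "19")
})

test_that("fits are deterministic and CV is seed-reproducible", {
  d <- make_shift_blocks(n = 20, p = 6, seed = 14)
  bd <- block_dataset(d$blocks, d$outcome)
  cfg <- integration_config(ncomp = 2, keepX = list(b1 = 3, b2 = 3),
                            cv_folds = 3, seed = 15)
  expect_identical(fit_block_splsda(bd, cfg)$loadings,
                   fit_block_splsda(bd, cfg)$loadings)
  expect_identical(cv_block_splsda(bd, cfg, repeats = 2)$per_repeat,
                   cv_block_splsda(bd, cfg, repeats = 2)$per_repeat)
})
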