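toy_features <- function(n_per = 5, p = 5, offset = 0, seed = 71,
                         offset_col = "alpha") {
  set.seed(seed)
  cols <- c("m_max", "r", "s0", "alpha", "beta")[seq_len(p)]
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, cols))
  X[seq_len(n_per), offset_col] <- X[seq_len(n_per), offset_col] + offset
  dplyr::bind_cols(
    tibble::tibble(animal_id = sprintf("t%02d", seq_len(2 * n_per)),
                   group = rep(c("g1", "g2"), each = n_per)),
    tibble::as_tibble(X))
}

test_that("the Fisher discriminant core agrees with MASS::lda", {
  skip_if_not_installed("MASS")
  feats <- toy_features(n_per = 6, offset = 1.5)
  X <- ppiscale:::feature_matrix(feats)
  grp1 <- feats$group == "g1"
  ours <- ppiscale:::fisher_lda(X, grp1)
  ref <- MASS::lda(X, grouping = feats$group, prior = c(0.5, 0.5))
  w_ref <- ref$scaling[, 1] / sqrt(sum(ref$scaling[, 1]^2))
  # directions are equal up to sign
  expect_equal(abs(sum(ours$normal * w_ref)), 1, tolerance = 1e-8)
  # and the lean permutation statistic matches the full computation
  expect_equal(ppiscale:::fisher_stat(X, grp1), ours$mean_abs_distance,
               tolerance = 1e-12)
})

test_that("a group offset in one feature concentrates the LD weight there", {
  # enough animals that the pooled covariance is well estimated
  feats <- toy_features(n_per = 12, offset = 6, offset_col = "alpha")
  res <- lda_condition(feats)
  expect_equal(names(which.max(abs(res$normal))), "alpha")
  null_scale <- lda_condition(toy_features(n_per = 12, offset = 0))$mean_abs_distance
  expect_gt(res$mean_abs_distance, null_scale)
  # strongly separated groups: the observed distance sits in the far tail
  # (unbalanced permutations of bimodal data tie with the observed statistic
  # occasionally, so the p-value is small but need not be the minimum)
  p <- permutation_distance_test(feats, n_perm = 500, seed = 72)
  expect_lt(p$p_value, 0.05)
})

test_that("LDA distance is invariant to feature order and affine rescaling", {
  feats <- toy_features(offset = 2)
  d1 <- lda_condition(feats)$mean_abs_distance
  reordered <- feats[, c("animal_id", "group", "beta", "s0", "alpha", "m_max", "r")]
  expect_equal(lda_condition(reordered)$mean_abs_distance, d1, tolerance = 1e-10)
  rescaled <- dplyr::mutate(feats, alpha = 100 * alpha - 7, s0 = -0.01 * s0)
  expect_equal(lda_condition(rescaled)$mean_abs_distance, d1, tolerance = 1e-10)
})

test_that("LOOCV accuracy is perfect for separated groups and near chance for identical ones", {
  sep <- toy_features(offset = 10)
  res <- loocv_accuracy_test(sep, n_perm = 200, seed = 73)
  expect_equal(res$accuracy, 1)
  expect_lt(res$p_value, 0.05)

  set.seed(74)
  accs <- vapply(1:40, function(i) {
    f <- toy_features(seed = 1000 + i)
    ppiscale:::loocv_accuracy(ppiscale:::feature_matrix(f), f$group == "g1")
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)

  null_res <- loocv_accuracy_test(toy_features(seed = 75), n_perm = 200, seed = 76)
  expect_gt(null_res$p_value, 0.05)
})

test_that("degenerate group layouts are refused", {
  one_each <- toy_features(n_per = 1)
  expect_error(lda_condition(one_each), class = "ppiscale_insufficient_data")
  three_groups <- dplyr::mutate(toy_features(), group = rep(c("a", "b", "c"),
                                                            length.out = 10))
  expect_error(lda_condition(three_groups), class = "ppiscale_domain_error")
})

test_that("permutation p-values are valid under the exchangeable null", {
  # meta-simulation: P(p <= x) should not exceed x by more than MC error
  set.seed(77)
  ps <- vapply(1:120, function(i) {
    f <- toy_features(seed = 2000 + i)
    permutation_distance_test(f, n_perm = 120, seed = 3000 + i)$p_value
  }, numeric(1))
  for (x in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= x), x + 1 / 121 + 3 * sqrt(x * (1 - x) / 120))
  }
})

test_that("the bootstrapped ratio test matches the exact binomial tail", {
  r0 <- ratio_multiplicity_test(0, 13, seed = 78)
  expect_gt(r0$p_value, 0.99)
  r_all <- ratio_multiplicity_test(13, 13, n_boot = 2000, seed = 79)
  expect_equal(r_all$p_value, 1 / 2001)
  r6 <- ratio_multiplicity_test(6, 13, n_boot = 10000, seed = 80)
  expect_equal(r6$p_exact, pbinom(5, 13, 0.05, lower.tail = FALSE), tolerance = 1e-15)
  # Monte-Carlo agreement with the exact tail
  expect_lt(abs(r6$p_value - (r6$p_exact + 1 / 10001)), 3e-4)
  expect_lt(r6$p_value, 1e-3)
})

test_that("PCA detects coupling structure and sign patterns", {
  # strong generative coupling: alpha tied to saturation, beta to threshold
  spec <- cohort_spec(n_animals = 30,
                      conditions = tibble::tibble(prepulse_db = 14,
                                                  delay_ms = 100,
                                                  condition_tag = "prepulse"))
  feats <- features_reduced(param_features(spec, seed = 81))
  pca <- pca_condition(feats, n_perm = 300, seed = 82)
  expect_lt(pca$p_value, 0.05)
  expect_lt(pca$weights[["alpha"]] * pca$weights[["saturation"]], 0)
  expect_lt(pca$weights[["beta"]] * pca$weights[["threshold"]], 0)

  # independent features: PC1 fraction modest, permutation p large
  set.seed(83)
  ind <- dplyr::bind_cols(
    tibble::tibble(animal_id = sprintf("i%02d", 1:40), group = "g"),
    tibble::as_tibble(matrix(rnorm(160), 40, 4,
                             dimnames = list(NULL, c("saturation", "threshold",
                                                     "alpha", "beta")))))
  pca_ind <- pca_condition(ind, n_perm = 300, seed = 84)
  expect_gt(pca_ind$p_value, 0.05)

  # perfectly collinear pair: PC1 carries at least half the variance
  coll <- dplyr::mutate(ind, beta = alpha)
  expect_gte(pca_condition(coll, n_perm = 50, seed = 85)$variance_fraction, 0.5)
})
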