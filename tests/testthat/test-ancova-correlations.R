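two_group_spec <- function(n_per = 8, offsets = list(), ...) {
  cohort_spec(groups = tibble::tibble(label = c("g1", "g2"), n = c(n_per, n_per)),
              conditions = tibble::tibble(prepulse_db = 14, delay_ms = 100,
                                          condition_tag = "prepulse"),
              group_offsets = offsets, ...)
}

test_that("the ANCOVA group p equals the explicit design-matrix F test", {
  # constructed data with identical covariate values in both groups, so the
  # covariate screen cannot exclude the condition
  set.seed(91)
  n <- 8
  covariate <- rep(seq(1.5, 2.5, length.out = n), 2)
  feats <- tibble::tibble(
    animal_id = sprintf("o%02d", 1:(2 * n)),
    group = rep(c("g1", "g2"), each = n),
    prepulse_db = 14, delay_ms = 100,
    saturation = covariate,
    threshold = rnorm(2 * n, 18, 2),
    alpha = 1.3 - 0.3 * covariate + rnorm(2 * n, 0, 0.05) +
      0.04 * rep(c(0, 1), each = n),
    beta = rnorm(2 * n, 0.9, 0.05))
  res <- ancova_scaling(feats, responses = "alpha")
  expect_false(res$excluded)
  # brute-force general linear model: F for group after the covariate
  y <- feats$alpha
  x <- feats$saturation
  g <- as.numeric(feats$group == "g2")
  X1 <- cbind(1, x, g)
  X0 <- cbind(1, x)
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  f_stat <- ((rss(X0) - rss(X1)) / 1) / (rss(X1) / (length(y) - ncol(X1)))
  p_oracle <- pf(f_stat, 1, length(y) - ncol(X1), lower.tail = FALSE)
  expect_equal(res$group_p, p_oracle, tolerance = 1e-8)
})

test_that("a heterogeneous-slopes interaction halts the ANCOVA stage", {
  set.seed(92)
  n <- 12
  feats <- tibble::tibble(
    animal_id = sprintf("h%02d", 1:(2 * n)),
    group = rep(c("g1", "g2"), each = n),
    prepulse_db = 14, delay_ms = 100,
    saturation = rep(seq(-1, 1, length.out = n), 2) + rnorm(2 * n, 0, 0.01),
    threshold = rnorm(2 * n),
    alpha = c(0.5 + 0.3 * seq(-1, 1, length.out = n),
              0.5 - 0.3 * seq(-1, 1, length.out = n)) + rnorm(2 * n, 0, 0.02),
    beta = rnorm(2 * n))
  res <- ancova_scaling(feats, responses = "alpha")
  expect_lt(res$interaction_p, 0.05)
  expect_true(is.na(res$group_p))
  expect_match(res$reason, "heterogeneous")
  expect_lt(res$slope_1 * res$slope_2, 0)
})

test_that("conditions with covariate group differences are excluded from ANCOVA", {
  feats <- features_reduced(param_features(
    two_group_spec(offsets = list(g2 = c(m_max = 3))), seed = 93))
  res <- ancova_scaling(feats, responses = "alpha")
  expect_true(res$excluded)
  expect_match(res$reason, "covariate")
  expect_true(is.na(res$group_p))
})

test_that("an alpha offset at matched baselines is detected by the ANCOVA", {
  hits <- vapply(1:20, function(i) {
    feats <- features_reduced(param_features(
      two_group_spec(n_per = 12, offsets = list(g2 = c(alpha = -0.12)),
                     alpha_condition_sd = 0.02), seed = 900 + i))
    res <- ancova_scaling(feats, responses = "alpha")
    !res$excluded && !is.na(res$group_p) && res$group_p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("across-animal correlations recover the generative coupling", {
  rs <- vapply(1:30, function(i) {
    feats <- features_reduced(param_features(
      cohort_spec(n_animals = 24,
                  conditions = tibble::tibble(prepulse_db = 14, delay_ms = 100,
                                              condition_tag = "prepulse"),
                  rho_alpha_mmax = -0.6), seed = 1100 + i))
    res <- scaling_baseline_correlation(feats)
    res$r[res$pair == "alpha_vs_saturation"]
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.6)), 0.1)

  rs0 <- vapply(1:30, function(i) {
    feats <- features_reduced(param_features(
      cohort_spec(n_animals = 24,
                  conditions = tibble::tibble(prepulse_db = 14, delay_ms = 100,
                                              condition_tag = "prepulse"),
                  rho_alpha_mmax = 0), seed = 1200 + i))
    res <- scaling_baseline_correlation(feats)
    res$r[res$pair == "alpha_vs_saturation"]
  }, numeric(1))
  expect_lt(abs(mean(rs0)), 0.07)
})

test_that("two-animal correlations are flagged as degenerate", {
  feats <- features_reduced(param_features(
    cohort_spec(n_animals = 2,
                conditions = tibble::tibble(prepulse_db = 14, delay_ms = 100,
                                            condition_tag = "prepulse")),
    seed = 94))
  res <- scaling_baseline_correlation(feats)
  expect_true(all(res$degenerate))
})

test_that("jitter robustness gives a degenerate band without noise and honest bands with it", {
  sc <- small_cohort()
  # near-zero SEM: every refit reproduces the same correlations
  summ0 <- dplyr::mutate(sc$summaries, sem = 1e-12)
  rb0 <- correlation_jitter_robustness(summ0, sc$fits, n_refit = 10,
                                       seed = 95)
  expect_lt(max(rb0$r_hi - rb0$r_lo, na.rm = TRUE), 1e-6)
  expect_equal(nrow(rb0), 13 * 2)
})

test_that("the within-animal null is computable and sane", {
  sc <- small_cohort()
  s1 <- dplyr::filter(sc$summaries, animal_id == "a01")
  nn <- within_animal_null(s1, sc$fits$fit[[1]], n_refit = 60, seed = 96)
  expect_equal(nrow(nn), 13 * 2)
  expect_true(all(abs(nn$r_null) <= 1 | is.na(nn$r_null)))
  # zero-noise data: degenerate null handled without crashing
  s0 <- dplyr::mutate(s1, sem = 0)
  f0 <- fit_animal(s0)
  nn0 <- within_animal_null(s0, f0, n_refit = 10, seed = 97)
  expect_true(all(is.na(nn0$r_null)))
})

test_that("scaling-versus-stimulus slopes recover the generative prepulse dependence", {
  sc <- small_cohort()
  res <- scaling_vs_stimulus_slopes(sc$fits, vary = "prepulse")
  # generator: alpha and beta decrease with prepulse level
  expect_true(all(res$slopes$slope[res$slopes$parameter == "alpha"] < 0))
  expect_lt(res$tests$mean_slope[res$tests$parameter == "alpha"], 0)

  res_d <- scaling_vs_stimulus_slopes(sc$fits, vary = "delay")
  expect_gt(res_d$tests$mean_slope[res_d$tests$parameter == "alpha"], 0)

  # constant scaling: slope distribution centred at zero
  set.seed(98)
  flat <- vapply(1:15, function(i) {
    spec <- cohort_spec(n_animals = 1, alpha_mean = 0.8, beta_mean = 0.9,
                        alpha_sd = 0, beta_sd = 0,
                        alpha_condition_sd = 0.01, beta_condition_sd = 0.01)
    feats <- param_features(spec, seed = 1300 + i)
    fits <- tibble::tibble(
      animal_id = "a01", group = "wt",
      fit = list(structure(list(animal_id = "a01", group = "wt",
                                m_max = 2, r = 0.25, s0 = 30, m0 = 0.1,
                                scalings = feats[, c("prepulse_db", "delay_ms",
                                                     "condition_tag", "alpha", "beta")],
                                variant = "both", rmse = 0, n_stimuli = 72,
                                n_params = 29, converged = TRUE),
                           class = "startle_fit")))
    scaling_vs_stimulus_slopes(fits, "prepulse")$slopes$slope[1]
  }, numeric(1))
  expect_gt(t.test(flat)$p.value, 0.05)

  # two conditions only: animal skipped with a warning
  two_cond <- cohort_spec(n_animals = 1,
                          conditions = tibble::tibble(prepulse_db = c(6, 14),
                                                      delay_ms = 100,
                                                      condition_tag = "prepulse"))
  feats2 <- param_features(two_cond, seed = 99)
  fits2 <- tibble::tibble(
    animal_id = "a01", group = "wt",
    fit = list(structure(list(animal_id = "a01", group = "wt", m_max = 2,
                              r = 0.25, s0 = 30, m0 = 0.1,
                              scalings = feats2[, c("prepulse_db", "delay_ms",
                                                    "condition_tag", "alpha", "beta")],
                              variant = "both", rmse = 0, n_stimuli = 17,
                              n_params = 7, converged = TRUE),
                         class = "startle_fit")))
  expect_warning(res2 <- scaling_vs_stimulus_slopes(fits2, "prepulse"), "skipped")
  expect_equal(nrow(res2$slopes), 0)
})
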