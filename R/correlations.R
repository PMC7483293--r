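#' Principal component structure of the reduced feature set
#'
#' Runs PCA on the standardized 4-feature table (saturation, threshold,
#' startle scaling, sound scaling) for one condition and reports the
#' fraction of variance explained by PC1 and its weights. Significance is
#' assessed by permutation: each feature column is shuffled independently
#' across animals (destroying between-feature coupling while preserving
#' marginals) and the PC1 variance fraction recomputed.
#'
#' @param features Reduced feature table for a single condition, >= 4 animals.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List of class `"ppi_pca"`: `variance_fraction`, `weights`,
#'   `p_value`, `n_perm`.
#' @export
pca_condition <- function(features, n_perm = 10000, seed = NULL) {
  X <- feature_matrix(features, standardize = TRUE)
  if (nrow(X) < 4) {
    abort("Need >= 4 animals for the PCA.", class = "ppiscale_insufficient_data")
  }
  const <- apply(X, 2, function(v) sample_sd(v) == 0)
  if (any(const)) {
    warn(sprintf("Dropping constant feature column(s): %s",
                 paste(colnames(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  pc1_fraction <- function(M) {
    ev <- prcomp(M, center = TRUE, scale. = FALSE)
    ev$sdev[1]^2 / sum(ev$sdev^2)
  }
  obs <- prcomp(X, center = TRUE, scale. = FALSE)
  obs_frac <- obs$sdev[1]^2 / sum(obs$sdev^2)
  null_stats <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      pc1_fraction(apply(X, 2, sample))
    }, numeric(1))
  })
  structure(list(variance_fraction = obs_frac,
                 weights = setNames(obs$rotation[, 1], colnames(X)),
                 p_value = perm_pvalue(null_stats, obs_frac),
                 n_perm = n_perm), class = "ppi_pca")
}

#' @export
print.ppi_pca <- function(x, ...) {
  cat(sprintf("<ppi_pca> PC1 explains %.1f%% of variance (p = %.4g)\n",
              100 * x$variance_fraction, x$p_value))
  print(round(x$weights, 3))
  invisible(x)
}

cor_or_na <- function(x, y) {
  if (sample_sd(x) == 0 || sample_sd(y) == 0 || length(x) < 3) {
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, degenerate = length(x) <= 2)
}

#' Scaling-versus-baseline correlations per condition
#'
#' For every prepulse condition, computes Pearson correlations across
#' animals between startle scaling and baseline saturation, and between
#' sound scaling and baseline threshold, together with the OLS regression
#' line for each pair.
#'
#' @param features Reduced feature table across conditions (>= 4 animals).
#' @return Tibble with one row per condition x pair: `pair`, `r`, `r2`,
#'   `p_value`, `slope`, `intercept`, `n`, `degenerate`.
#' @export
scaling_baseline_correlation <- function(features) {
  assert_cols(features, c("animal_id", "prepulse_db", "delay_ms",
                          "saturation", "threshold", "alpha", "beta"),
              "reduced feature table")
  one_pair <- function(d, xcol, ycol, pair) {
    x <- d[[xcol]]; y <- d[[ycol]]
    ct <- cor_or_na(x, y)
    slope <- if (sample_sd(x) > 0) ols_slope(x, y) else NA_real_
    tibble(pair = pair, r = ct$r, r2 = ct$r^2, p_value = ct$p,
           slope = slope,
           intercept = if (is.na(slope)) NA_real_ else mean(y) - slope * mean(x),
           n = nrow(d), degenerate = isTRUE(ct$degenerate) || nrow(d) < 4)
  }
  features %>%
    group_by(across(all_of(intersect(c("condition_tag", "prepulse_db", "delay_ms"),
                                     names(features))))) %>%
    dplyr::group_modify(function(d, key) {
      bind_rows(one_pair(d, "saturation", "alpha", "alpha_vs_saturation"),
                one_pair(d, "threshold", "beta", "beta_vs_threshold"))
    }) %>%
    ungroup()
}

# Refit every animal once to jittered summaries (warm start at its fit) and
# return the reduced features. Shared by the robustness and null analyses.
refit_jittered_cohort <- function(dats, fits, config) {
  purrr::map2(dats, fits$fit, function(dat, f) {
    dat$y <- jitter_summaries(dat$y, dat$sem)
    m0 <- if (length(dat$m0_rows) > 0) max(mean(dat$y[dat$m0_rows]), 0) else dat$m0
    start <- c(f$m_max, f$r, f$s0, f$scalings$alpha,
               if (f$variant == "both") f$scalings$beta)
    res <- fit_core(dat, f$variant, config, m0 = m0, start = start)
    k <- nrow(dat$conds)
    tibble(animal_id = f$animal_id,
           prepulse_db = dat$conds$prepulse_db, delay_ms = dat$conds$delay_ms,
           saturation = res$par[[1]],
           threshold = res$par[[3]] - log(19) / res$par[[2]],
           alpha = unname(res$par[3 + seq_len(k)]),
           beta = if (f$variant == "both") unname(res$par[3 + k + seq_len(k)]) else 1,
           converged = res$converged)
  }) %>% bind_rows()
}

#' Robustness of across-animal correlations to startle noise
#'
#' Repeatedly jitters every animal's movement summaries (Gaussian, SD equal
#' to each stimulus's SEM), refits all animals, and recomputes the
#' across-animal scaling-versus-baseline correlations, yielding a
#' distribution of correlation values attributable to measurement noise.
#' The zero-crossing fraction — the fraction of refits in which the
#' correlation lands on the opposite side of zero from the observed value —
#' measures how likely a correlation of r = 0 (or of opposite sign) would be.
#'
#' @param summaries Movement summaries for all animals.
#' @param fits Cohort fit table from [fit_cohort()].
#' @param n_refit Number of jittered cohort refits.
#' @param config A [fit_config()].
#' @param seed RNG seed.
#' @return Tibble per condition x pair: observed `r`, percentile band
#'   (`r_lo`, `r_median`, `r_hi`, 5th/50th/95th), `zero_crossing` fraction
#'   and `n_refit`; failed refits are excluded with their count in
#'   `n_failed`.
#' @export
correlation_jitter_robustness <- function(summaries, fits, n_refit = 10000,
                                          config = fit_config(), seed = NULL) {
  dats <- summaries %>%
    dplyr::group_split(.data$animal_id) %>%
    purrr::map(build_fit_data, quiet = TRUE)
  stopifnot(length(dats) == nrow(fits))
  observed <- scaling_baseline_correlation(condition_features(fits, "reduced")) %>%
    select(dplyr::any_of(c("condition_tag", "prepulse_db", "delay_ms")),
           "pair", r_observed = "r")
  reps <- with_seed_if(seed, {
    purrr::map(seq_len(n_refit), function(i) {
      feats <- refit_jittered_cohort(dats, fits, config)
      n_bad <- sum(!feats$converged)
      scaling_baseline_correlation(mutate(feats, group = "all")) %>%
        mutate(refit = i, n_bad = n_bad)
    })
  }) %>% bind_rows()
  reps %>%
    group_by(.data$prepulse_db, .data$delay_ms, .data$pair) %>%
    summarise(r_lo = quantile(.data$r, 0.05, na.rm = TRUE),
              r_median = stats::median(.data$r, na.rm = TRUE),
              r_hi = quantile(.data$r, 0.95, na.rm = TRUE),
              r_draws = list(.data$r),
              n_refit = dplyr::n(), .groups = "drop") %>%
    left_join(observed, by = intersect(c("prepulse_db", "delay_ms", "pair"),
                                       names(observed))) %>%
    mutate(zero_crossing = purrr::map2_dbl(.data$r_draws, .data$r_observed,
                                           function(rs, r0) mean(sign(rs) != sign(r0), na.rm = TRUE))) %>%
    select(-"r_draws")
}

#' Within-animal null distribution of parameter-pair correlations
#'
#' Compensation control: sigmoid parameters can trade off against each other
#' under noise, creating spurious parameter correlations. For a single
#' animal, this refits the model to jittered data many times and computes,
#' across refits, the correlation between each condition's startle scaling
#' and the saturation, and between each condition's sound scaling and the
#' threshold. Pooled across animals, these within-animal correlations form
#' the null distribution against which observed across-animal correlations
#' are judged: an across-animal correlation exceeding the null's 75th
#' percentile (in magnitude, respecting sign) is not attributable to
#' compensation.
#'
#' @param summaries Movement summaries for one animal.
#' @param fit The animal's `startle_fit`.
#' @param n_refit Number of jittered refits (default 1,000).
#' @param config A [fit_config()].
#' @param seed RNG seed.
#' @return Tibble per condition x pair: `r_null` (correlation across
#'   refits), `n_refit`, `n_failed`.
#' @export
within_animal_null <- function(summaries, fit, n_refit = 1000,
                               config = fit_config(), seed = NULL) {
  dat <- build_fit_data(summaries, quiet = TRUE)
  k <- nrow(dat$conds)
  start <- c(fit$m_max, fit$r, fit$s0, fit$scalings$alpha,
             if (fit$variant == "both") fit$scalings$beta)
  y0 <- dat$y
  draws <- with_seed_if(seed, {
    vapply(seq_len(n_refit), function(i) {
      dat$y <- jitter_summaries(y0, dat$sem)
      m0 <- if (length(dat$m0_rows) > 0) max(mean(dat$y[dat$m0_rows]), 0) else dat$m0
      res <- fit_core(dat, fit$variant, config, m0 = m0, start = start)
      c(res$par, ok = as.numeric(res$converged))
    }, numeric(length(start) + 1))
  })
  ok <- draws["ok", ] > 0
  d <- draws[, ok, drop = FALSE]
  sat <- d[1, ]
  thr <- d[3, ] - log(19) / d[2, ]
  safe_cor <- function(x, y) {
    if (sample_sd(x) == 0 || sample_sd(y) == 0) NA_real_ else cor(x, y)
  }
  purrr::map(seq_len(k), function(ci) {
    a <- d[3 + ci, ]
    b <- if (fit$variant == "both") d[3 + k + ci, ] else rep(1, ncol(d))
    tibble(animal_id = fit$animal_id,
           prepulse_db = dat$conds$prepulse_db[ci],
           delay_ms = dat$conds$delay_ms[ci],
           pair = c("alpha_vs_saturation", "beta_vs_threshold"),
           r_null = c(safe_cor(a, sat), safe_cor(b, thr)),
           n_refit = n_refit, n_failed = sum(!ok))
  }) %>% bind_rows()
}
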