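#' Cross-validate the two model variants for one animal
#'
#' Compares the model with both startle and sound scaling against the
#' startle-scaling-only model by repeated 80/20 cross-validation. By default
#' trials are split within each stimulus, so every stimulus contributes to
#' both the training summaries and the held-out test summaries; the
#' `"stimulus"` unit in [fit_config()] holds out whole stimulus-mean points
#' instead. Both variants are fit to the training summaries and scored by
#' [normalized_error()] on the held-out summaries; the reported errors are
#' means over iterations, and a positive `error_difference`
#' (startle-only minus both) means the two-scaling model generalizes better.
#'
#' @param trials Trial-level movements for one animal (see
#'   [trial_movements()]); each stimulus should have >= 5 trials so the 20%
#'   holdout is non-empty.
#' @param config A [fit_config()].
#' @param seed Seed for the random splits (defaults to `config$seed`).
#' @return One-row tibble: `cv_error_both`, `cv_error_startle_only`,
#'   `error_difference`, `n_iterations`; the per-iteration errors are
#'   attached as attribute `"iterations"`.
#' @export
cross_validate <- function(trials, config = fit_config(), seed = config$seed) {
  assert_cols(trials, c("animal_id", "startle_db", "prepulse_db", "delay_ms",
                        "log_movement"), "trial movement table")
  if (dplyr::n_distinct(trials$animal_id) != 1) {
    abort("cross_validate() expects trials from a single animal.",
          class = "ppiscale_schema_error")
  }
  stim_key <- paste(trials$prepulse_db, trials$delay_ms, trials$startle_db)
  stim_n <- table(stim_key)
  if (any(stim_n < 5)) {
    warn(sprintf("%d stimuli have < 5 trials; holdout still uses >= 1 trial.",
                 sum(stim_n < 5)))
  }
  idx_by_stim <- split(seq_len(nrow(trials)), stim_key)
  one_iter <- function() {
    if (config$cv_unit == "trial") {
      test_idx <- unlist(lapply(idx_by_stim, function(ix) {
        n_hold <- max(1L, round((1 - config$cv_fraction) * length(ix)))
        sample(ix, n_hold)
      }), use.names = FALSE)
    } else {
      stims <- names(idx_by_stim)
      n_hold <- max(1L, round((1 - config$cv_fraction) * length(stims)))
      test_idx <- unlist(idx_by_stim[sample(stims, n_hold)], use.names = FALSE)
    }
    train <- trials[-test_idx, , drop = FALSE]
    test <- trials[test_idx, , drop = FALSE]
    train_sum <- suppressWarnings(summarize_movement(train))
    test_sum <- suppressWarnings(summarize_movement(test))
    fits <- lapply(c("both", "startle_only"), function(v) {
      suppressWarnings(fit_animal(train_sum, config, variant = v))
    })
    vapply(fits, function(f) suppressWarnings(normalized_error(f, test_sum)),
           numeric(1))
  }
  errs <- with_seed_if(seed, {
    vapply(seq_len(config$cv_iterations), function(i) one_iter(), numeric(2))
  })
  iter_tbl <- tibble(iteration = seq_len(config$cv_iterations),
                     error_both = errs[1, ], error_startle_only = errs[2, ])
  out <- tibble(animal_id = trials$animal_id[[1]],
                cv_error_both = mean(errs[1, ]),
                cv_error_startle_only = mean(errs[2, ]),
                error_difference = mean(errs[2, ]) - mean(errs[1, ]),
                n_iterations = config$cv_iterations)
  attr(out, "iterations") <- iter_tbl
  out
}

#' Cross-validate every animal in a cohort
#'
#' @param trials Trial-level movements for several animals.
#' @inheritParams cross_validate
#' @return Tibble with one row per animal (see [cross_validate()]).
#' @export
cross_validate_cohort <- function(trials, config = fit_config(),
                                  seed = config$seed) {
  pieces <- dplyr::group_split(trials, .data$animal_id)
  seeds <- child_seeds(seed, length(pieces))
  purrr::map2(pieces, seeds, function(d, s) {
    res <- cross_validate(d, config, seed = s)
    if ("group" %in% names(d)) res$group <- d$group[[1]]
    res
  }) %>% bind_rows()
}

#' Swap fitted parameter sets between animals
#'
#' Evaluates how distinct each animal's fitted parameters are by scoring
#' every animal's movement summaries under every other animal's best-fit
#' parameter set (including its floor `m0`) with [normalized_error()], and
#' comparing against the self-fit error. Pairs whose stimulus designs or
#' condition sets do not match are skipped with a warning.
#'
#' @param fits Cohort fit table from [fit_cohort()].
#' @param summaries Movement summaries for the same animals.
#' @return List of class `"ppi_swap"`: `pairs` (per ordered pair error),
#'   `per_animal` (self error and median swapped error), and `summary`
#'   (cohort medians and the median error increase).
#' @export
swap_parameters <- function(fits, summaries) {
  assert_cols(fits, c("animal_id", "fit"), "fit table")
  ids <- fits$animal_id
  if (length(ids) < 2) {
    warn("Fewer than 2 animals: no swaps possible.")
    return(structure(list(pairs = tibble(animal_id = character(),
                                         donor_id = character(),
                                         error = numeric()),
                          per_animal = tibble(), summary = tibble()),
                     class = "ppi_swap"))
  }
  summ_by <- split(summaries, summaries$animal_id)
  n_skipped <- 0
  rows <- list()
  for (i in seq_along(ids)) {
    si <- summ_by[[as.character(ids[i])]]
    for (j in seq_along(ids)) {
      err <- tryCatch(
        suppressWarnings(normalized_error(fits$fit[[j]], si)),
        ppiscale_condition_mismatch = function(e) NA_real_)
      if (i != j && is.na(err)) n_skipped <- n_skipped + 1
      rows[[length(rows) + 1]] <- tibble(animal_id = ids[i], donor_id = ids[j],
                                         error = err, self = i == j)
    }
  }
  if (n_skipped > 0) {
    warn(sprintf("%d animal pairs skipped (mismatched stimulus designs).", n_skipped))
  }
  pairs <- bind_rows(rows)
  per_animal <- pairs %>%
    group_by(.data$animal_id) %>%
    summarise(self_error = .data$error[.data$self],
              median_swapped = stats::median(.data$error[!.data$self], na.rm = TRUE),
              .groups = "drop") %>%
    mutate(increase = .data$median_swapped - .data$self_error)
  test <- tryCatch(
    suppressWarnings(stats::wilcox.test(per_animal$median_swapped,
                                        per_animal$self_error,
                                        paired = TRUE, alternative = "greater")),
    error = function(e) list(p.value = NA_real_))
  summary <- tibble(median_self = stats::median(per_animal$self_error, na.rm = TRUE),
                    median_swapped = stats::median(per_animal$median_swapped, na.rm = TRUE),
                    median_increase = stats::median(per_animal$increase, na.rm = TRUE),
                    p_value = test$p.value)
  structure(list(pairs = filter(pairs, !.data$self) %>% select(-"self"),
                 per_animal = per_animal, summary = summary),
            class = "ppi_swap")
}

#' @export
print.ppi_swap <- function(x, ...) {
  cat("<ppi_swap>\n")
  print(x$summary)
  invisible(x)
}

# Jitter a summary table once: every mean_log_movement perturbed by an
# independent Gaussian draw with SD equal to that stimulus's SEM.
jitter_summaries <- function(y, sem) y + rnorm(length(y), 0, sem)

#' Jittered-refit confidence intervals for model parameters
#'
#' Refits the model many times to jittered data, in which each stimulus mean
#' is perturbed by a Gaussian draw with standard deviation equal to its
#' standard error (the floor `m0` is re-estimated from the jittered 0-dB
#' stimuli each time). The confidence interval for each parameter spans the
#' chosen percentiles (default 5th-95th, a 90% interval) across refits.
#' Refits warm-start at the point estimate.
#'
#' @param summaries Movement summaries for one animal (finite `sem` required).
#' @param fit The animal's `startle_fit` (point estimate and warm start).
#' @param config A [fit_config()]; `jitter_refits` and `ci_probs` are used.
#' @param n_refit Number of refits (defaults to `config$jitter_refits`).
#' @param seed Seed for the jitter draws.
#' @return List of class `"ppi_ci"`: `intervals` (term, estimate, lower,
#'   upper), the matrix of refit `draws`, and `n_failed`.
#' @export
jitter_confidence <- function(summaries, fit, config = fit_config(),
                              n_refit = config$jitter_refits,
                              seed = config$seed) {
  dat <- build_fit_data(summaries, quiet = TRUE)
  if (any(!is.finite(dat$sem))) {
    abort("All summaries need a finite SEM to be jittered.",
          class = "ppiscale_domain_error")
  }
  k <- nrow(dat$conds)
  start <- c(fit$m_max, fit$r, fit$s0, fit$scalings$alpha,
             if (fit$variant == "both") fit$scalings$beta)
  y0 <- dat$y
  draws <- with_seed_if(seed, {
    vapply(seq_len(n_refit), function(i) {
      dat$y <- jitter_summaries(y0, dat$sem)
      m0 <- if (length(dat$m0_rows) > 0) max(mean(dat$y[dat$m0_rows]), 0) else dat$m0
      res <- fit_core(dat, fit$variant, config, m0 = m0, start = start)
      c(res$par, m0 = m0, ok = as.numeric(res$converged))
    }, numeric(length(start) + 2))
  })
  ok <- draws["ok", ] > 0
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * n_refit) {
    warn(sprintf("%d of %d jittered refits failed to converge.", n_failed, n_refit))
  }
  par_names <- c("m_max", "r", "s0",
                 if (k > 0) paste0("alpha_", condition_label(dat$conds$prepulse_db,
                                                             dat$conds$delay_ms)),
                 if (fit$variant == "both" && k > 0)
                   paste0("beta_", condition_label(dat$conds$prepulse_db,
                                                   dat$conds$delay_ms)))
  keep <- draws[seq_along(start), ok, drop = FALSE]
  rownames(keep) <- par_names
  thr <- keep["s0", ] - log(19) / keep["r", ]
  keep <- rbind(keep, threshold = thr)
  est <- c(start, baseline_threshold(fit$r, fit$s0))
  qs <- apply(keep, 1, quantile, probs = config$ci_probs, names = FALSE)
  intervals <- tibble(term = rownames(keep), estimate = est,
                      lower = qs[1, ], upper = qs[2, ])
  structure(list(intervals = intervals, draws = t(keep), n_failed = n_failed,
                 n_refit = n_refit, animal_id = fit$animal_id),
            class = "ppi_ci")
}

#' @export
print.ppi_ci <- function(x, ...) {
  cat(sprintf("<ppi_ci> animal %s: %d refits (%d failed)\n",
              x$animal_id, x$n_refit, x$n_failed))
  print(x$intervals, n = Inf)
  invisible(x)
}
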