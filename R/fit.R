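#' Fitting configuration
#'
#' Collects the tunable knobs of the model-fitting machinery. Defaults follow
#' the analysis protocol: 80/20 cross-validation with 100 iterations, 10,000
#' jittered refits for 90% confidence intervals (5th-95th percentile), and
#' three perturbed optimizer restarts on non-convergence.
#'
#' @param cv_fraction Fraction of trials used for training in each
#'   cross-validation iteration.
#' @param cv_iterations Number of cross-validation iterations.
#' @param cv_unit `"trial"` resamples trials within each stimulus (every
#'   stimulus appears in both train and test); `"stimulus"` holds out whole
#'   stimulus-mean points.
#' @param jitter_refits Number of jittered refits for confidence intervals.
#' @param ci_probs Lower/upper percentile of the jitter distribution.
#' @param restarts Perturbed restarts after a failed optimization.
#' @param maxiter,ftol,ptol Levenberg-Marquardt control parameters.
#' @param seed Default seed for stochastic procedures (`NULL` = ambient RNG).
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(cv_fraction = 0.8, cv_iterations = 100,
                       cv_unit = c("trial", "stimulus"),
                       jitter_refits = 10000, ci_probs = c(0.05, 0.95),
                       restarts = 3, maxiter = 200, ftol = 1e-10, ptol = 1e-10,
                       seed = NULL) {
  stopifnot(cv_fraction > 0, cv_fraction < 1, cv_iterations >= 1,
            jitter_refits >= 1, length(ci_probs) == 2)
  structure(list(cv_fraction = cv_fraction, cv_iterations = cv_iterations,
                 cv_unit = match.arg(cv_unit), jitter_refits = jitter_refits,
                 ci_probs = sort(ci_probs), restarts = restarts,
                 maxiter = maxiter, ftol = ftol, ptol = ptol, seed = seed),
            class = "fit_config")
}

# ---- internal fitting machinery -------------------------------------------

# Flatten one animal's movement summaries into the vectors the optimizer
# needs: sound levels, observed means, SEMs, a 0-based condition index
# (0 = baseline), the condition table, and the fixed floor m0 (mean log
# movement over 0-dB no-prepulse stimuli).
build_fit_data <- function(summaries, quiet = FALSE) {
  assert_cols(summaries, c("animal_id", "prepulse_db", "delay_ms",
                           "startle_db", "mean_log_movement"), "summary table")
  if (dplyr::n_distinct(summaries$animal_id) != 1) {
    abort("Summaries must belong to a single animal.", class = "ppiscale_schema_error")
  }
  summaries <- arrange(summaries, !is_baseline_condition(.data$prepulse_db),
                       .data$prepulse_db, .data$delay_ms, .data$startle_db)
  is_base <- is_baseline_condition(summaries$prepulse_db)
  conds <- summaries[!is_base, c("prepulse_db", "delay_ms")] %>%
    distinct() %>% arrange(.data$prepulse_db, .data$delay_ms)
  cond_idx <- integer(nrow(summaries))
  if (nrow(conds) > 0) {
    key <- paste(summaries$prepulse_db, summaries$delay_ms)
    ckey <- paste(conds$prepulse_db, conds$delay_ms)
    cond_idx[!is_base] <- match(key[!is_base], ckey)
    if ("condition_tag" %in% names(summaries)) {
      conds$condition_tag <- summaries$condition_tag[!is_base][match(ckey, key[!is_base])]
    }
  }
  m0_rows <- which(is_base & summaries$startle_db == 0)
  m0 <- if (length(m0_rows) > 0) mean(summaries$mean_log_movement[m0_rows]) else {
    if (!quiet) warn("No 0-dB baseline stimuli: m0 set to 0.")
    0
  }
  list(s = summaries$startle_db, y = summaries$mean_log_movement,
       sem = if ("sem" %in% names(summaries)) summaries$sem else rep(NA_real_, nrow(summaries)),
       cond = cond_idx, conds = conds, is_base = is_base, m0 = max(m0, 0),
       m0_rows = m0_rows, animal_id = summaries$animal_id[[1]],
       group = if ("group" %in% names(summaries)) summaries$group[[1]] else NA_character_,
       n_baseline_levels = dplyr::n_distinct(summaries$startle_db[is_base]))
}

model_pred <- function(theta, dat, variant, m0) {
  k <- nrow(dat$conds)
  m_max <- theta[1]; r <- theta[2]; s0 <- theta[3]
  a <- c(1, theta[3 + seq_len(k)])[dat$cond + 1L]
  b <- if (variant == "both") c(1, theta[3 + k + seq_len(k)])[dat$cond + 1L] else 1
  m0 + a * startle_sigmoid(b * dat$s, m_max, r, s0)
}

model_resid <- function(theta, dat, variant, m0) {
  model_pred(theta, dat, variant, m0) - dat$y
}

model_jac <- function(theta, dat, variant, m0) {
  k <- nrow(dat$conds)
  m_max <- theta[1]; r <- theta[2]; s0 <- theta[3]
  a <- c(1, theta[3 + seq_len(k)])[dat$cond + 1L]
  b <- if (variant == "both") c(1, theta[3 + k + seq_len(k)])[dat$cond + 1L] else rep(1, length(dat$s))
  u <- b * dat$s
  e <- exp(-r * (u - s0)); d <- 1 + e
  nn <- m_max / d
  g <- nn * e / d                      # dN/d(-exponent argument) common factor
  npar <- if (variant == "both") 3 + 2 * k else 3 + k
  jac <- matrix(0, length(dat$s), npar)
  jac[, 1] <- a / d                    # d/d m_max
  jac[, 2] <- a * g * (u - s0)         # d/d r
  jac[, 3] <- -a * g * r               # d/d s0
  if (k > 0) {
    rows <- which(dat$cond > 0)
    jac[cbind(rows, 3 + dat$cond[rows])] <- nn[rows]          # d/d alpha_c
    if (variant == "both") {
      jac[cbind(rows, 3 + k + dat$cond[rows])] <-
        a[rows] * g[rows] * r * dat$s[rows]                   # d/d beta_c
    }
  }
  jac
}

# Fit the sigmoid to baseline-condition summaries alone; used to initialize
# the joint fit.
init_baseline <- function(dat) {
  yb <- dat$y[dat$is_base] - dat$m0
  sb <- dat$s[dat$is_base]
  m_max0 <- max(max(yb), 0.1)
  half <- m_max0 / 2
  s00 <- if (any(yb >= half)) sb[which(yb >= half)[1]] else mean(range(sb))
  c(m_max = m_max0, r = 0.2, s0 = s00)
}

fit_bounds <- function(dat, variant) {
  k <- nrow(dat$conds)
  y_cap <- max(4 * max(abs(dat$y - dat$m0)), 1)
  lower <- c(1e-4, 1e-4, min(dat$s) - 20)
  upper <- c(y_cap, 2, max(dat$s) + 20)
  n_scale <- if (variant == "both") 2 * k else k
  list(lower = c(lower, rep(0, n_scale)), upper = c(upper, rep(1, n_scale)))
}

fit_core <- function(dat, variant, config, m0 = dat$m0, start = NULL) {
  k <- nrow(dat$conds)
  bounds <- fit_bounds(dat, variant)
  if (is.null(start)) {
    base_dat <- list(s = dat$s[dat$is_base], y = dat$y[dat$is_base],
                     cond = integer(sum(dat$is_base)), conds = dat$conds[0, ],
                     is_base = rep(TRUE, sum(dat$is_base)))
    b0 <- init_baseline(dat)
    base_fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(b0, bounds$lower[1:3]), bounds$upper[1:3]),
      lower = bounds$lower[1:3], upper = bounds$upper[1:3],
      fn = model_resid, jac = model_jac, dat = base_dat, variant = variant, m0 = m0,
      control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                           ftol = config$ftol, ptol = config$ptol)),
      silent = TRUE)
    b_init <- if (inherits(base_fit, "try-error")) b0 else coef(base_fit)
    start <- c(b_init, rep(1, if (variant == "both") 2 * k else k))
  }
  start <- pmin(pmax(start, bounds$lower), bounds$upper)
  run_once <- function(par0) {
    try(minpack.lm::nls.lm(
      par = par0, lower = bounds$lower, upper = bounds$upper,
      fn = model_resid, jac = model_jac, dat = dat, variant = variant, m0 = m0,
      control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                           ftol = config$ftol, ptol = config$ptol)),
      silent = TRUE)
  }
  ok <- function(f) !inherits(f, "try-error") && is.finite(f$deviance) &&
    f$info %in% c(1, 2, 3, 4)
  fit <- run_once(start)
  tries <- 0
  best <- fit
  while (!ok(best) && tries < config$restarts) {
    tries <- tries + 1
    jit <- start * (1 + stats::runif(length(start), -0.2, 0.2)) +
      stats::runif(length(start), -0.05, 0.05)
    cand <- run_once(pmin(pmax(jit, bounds$lower), bounds$upper))
    if (!inherits(cand, "try-error") &&
        (inherits(best, "try-error") || cand$deviance < best$deviance)) best <- cand
  }
  if (inherits(best, "try-error")) {
    return(list(par = start, rmse = NA_real_, converged = FALSE, info = NA_integer_))
  }
  list(par = coef(best), rmse = sqrt(best$deviance / length(dat$y)),
       converged = ok(best), info = best$info)
}

# ---- user-facing fitting ---------------------------------------------------

#' Fit the startle scaling model to one animal
#'
#' Jointly fits the three baseline sigmoid parameters and a pair of scaling
#' parameters per prepulse condition (or only the startle scaling, for the
#' `"startle_only"` variant) to all of an animal's movement summaries, by
#' bounded nonlinear least squares on the stacked residuals (equivalent to
#' minimizing the total root-mean-squared error across all stimuli).
#'
#' Scaling parameters start at 1 (no scaling) and are bounded to \[0, 1\];
#' the baseline parameters are initialized from a sigmoid fit to the
#' no-prepulse summaries alone. The sound-independent floor `m0` is estimated
#' as the mean log movement over 0-dB no-prepulse stimuli and held fixed
#' (0 with a warning when no such stimuli exist).
#'
#' @param summaries Movement summaries for one animal (see
#'   [summarize_movement()]) spanning at least 4 baseline startle levels.
#' @param config A [fit_config()].
#' @param variant `"both"` (startle and sound scaling) or `"startle_only"`.
#' @param start Optional full start vector (used internally for warm starts).
#' @return An object of class `"startle_fit"`: baseline parameters, a
#'   `scalings` tibble with per-condition `alpha`/`beta`, the total `rmse`,
#'   and convergence diagnostics. Supports [tidy()], [glance()], [predict()]
#'   and [autoplot()].
#' @export
fit_animal <- function(summaries, config = fit_config(),
                       variant = c("both", "startle_only"), start = NULL) {
  variant <- match.arg(variant)
  dat <- build_fit_data(summaries)
  if (dat$n_baseline_levels < 4) {
    abort("Need baseline summaries at >= 4 startle levels to anchor the sigmoid.",
          class = "ppiscale_insufficient_design")
  }
  degenerate <- sample_sd(dat$y) < 1e-10
  if (degenerate) warn("Flat movement data: sigmoid parameters are unidentifiable.")
  res <- fit_core(dat, variant, config, start = start)
  k <- nrow(dat$conds)
  scalings <- dat$conds
  scalings$alpha <- if (k > 0) unname(res$par[3 + seq_len(k)]) else numeric(0)
  scalings$beta <- if (variant == "both" && k > 0) {
    unname(res$par[3 + k + seq_len(k)])
  } else rep(1, k)
  structure(list(
    animal_id = dat$animal_id, group = dat$group,
    m_max = unname(res$par[[1]]), r = unname(res$par[[2]]),
    s0 = unname(res$par[[3]]), m0 = dat$m0,
    scalings = as_tibble(scalings), variant = variant,
    rmse = res$rmse, n_stimuli = length(dat$y),
    n_params = length(res$par),
    converged = res$converged && !degenerate, degenerate = degenerate,
    info = res$info), class = "startle_fit")
}

#' Fit the startle scaling model to every animal in a cohort
#'
#' @param summaries Movement summaries for one or more animals.
#' @inheritParams fit_animal
#' @return Tibble with one row per animal: `animal_id`, `group`, the fit
#'   object in a `fit` list-column, `rmse` and `converged`.
#' @export
fit_cohort <- function(summaries, config = fit_config(),
                       variant = c("both", "startle_only")) {
  variant <- match.arg(variant)
  summaries %>%
    dplyr::group_split(.data$animal_id) %>%
    purrr::map(function(d) {
      f <- fit_animal(d, config, variant)
      tibble(animal_id = f$animal_id, group = f$group, fit = list(f),
             rmse = f$rmse, converged = f$converged)
    }) %>%
    bind_rows()
}

#' @export
print.startle_fit <- function(x, ...) {
  cat(sprintf("<startle_fit> animal %s (%s)\n", x$animal_id, x$variant))
  cat(sprintf("  baseline: m_max = %.3f, r = %.3f, s0 = %.2f, m0 = %.3f (threshold %.2f dB)\n",
              x$m_max, x$r, x$s0, x$m0, baseline_threshold(x$r, x$s0)))
  cat(sprintf("  %d condition(s); rmse = %.4g; converged: %s\n",
              nrow(x$scalings), x$rmse, x$converged))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.startle_fit <- function(x, ...) {
  base <- tibble(term = c("m_max", "r", "s0", "m0", "threshold"),
                 estimate = c(x$m_max, x$r, x$s0, x$m0,
                              baseline_threshold(x$r, x$s0)),
                 prepulse_db = NA_real_, delay_ms = NA_real_,
                 percent_scaling = NA_real_)
  if (nrow(x$scalings) == 0) return(base)
  sc <- x$scalings %>%
    tidyr::pivot_longer(c("alpha", "beta"), names_to = "term",
                        values_to = "estimate") %>%
    mutate(percent_scaling = percent_scaling(.data$estimate)) %>%
    select("term", "estimate", "prepulse_db", "delay_ms", "percent_scaling")
  bind_rows(base, sc)
}

#' @exportS3Method generics::glance
glance.startle_fit <- function(x, ...) {
  tibble(animal_id = x$animal_id, variant = x$variant, rmse = x$rmse,
         n_stimuli = x$n_stimuli, n_conditions = nrow(x$scalings),
         n_params = x$n_params, converged = x$converged, m0 = x$m0)
}

#' Predict mean log movement for stimuli
#'
#' @param object A `startle_fit`.
#' @param newdata Tibble with `startle_db`, `prepulse_db`, `delay_ms`.
#' @param ... Unused.
#' @return Numeric vector of predicted mean log movements.
#' @export
predict.startle_fit <- function(object, newdata, ...) {
  assert_cols(newdata, c("startle_db", "prepulse_db", "delay_ms"), "newdata")
  is_base <- is_baseline_condition(newdata$prepulse_db)
  a <- rep(1, nrow(newdata)); b <- rep(1, nrow(newdata))
  if (any(!is_base)) {
    key <- paste(newdata$prepulse_db, newdata$delay_ms)
    ckey <- paste(object$scalings$prepulse_db, object$scalings$delay_ms)
    idx <- match(key[!is_base], ckey)
    if (anyNA(idx)) {
      abort("newdata contains prepulse conditions absent from the fit.",
            class = "ppiscale_condition_mismatch")
    }
    a[!is_base] <- object$scalings$alpha[idx]
    b[!is_base] <- object$scalings$beta[idx]
  }
  predicted_movement(newdata$startle_db, object$m_max, object$r, object$s0,
                     alpha = a, beta = b, m0 = object$m0, variant = object$variant)
}

#' SEM-normalized root-mean-squared prediction error
#'
#' Measures the deviation between the model and held-out movement summaries
#' in units of each stimulus's standard error:
#' `sqrt(mean(((prediction - mean_log_movement) / sem)^2))`. Stimuli with a
#' zero or undefined SEM carry no usable scale and are excluded with a
#' warning.
#'
#' @param fit A `startle_fit`.
#' @param test_summaries Movement summaries to evaluate against (must carry
#'   a `sem` column).
#' @return The normalized RMSE (dimensionless).
#' @export
normalized_error <- function(fit, test_summaries) {
  assert_cols(test_summaries, c("startle_db", "prepulse_db", "delay_ms",
                                "mean_log_movement", "sem"), "test summaries")
  pred <- predict(fit, test_summaries)
  z <- (pred - test_summaries$mean_log_movement) / test_summaries$sem
  bad <- !is.finite(z)
  if (any(bad)) {
    warn(sprintf("%d stimuli with zero/undefined SEM excluded from the normalized error.",
                 sum(bad)))
    z <- z[!bad]
  }
  if (length(z) == 0) {
    abort("No stimuli with a positive SEM to evaluate.",
          class = "ppiscale_insufficient_data")
  }
  sqrt(mean(z^2))
}
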