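#' Fit the per-session accelerometer baseline
#'
#' For each (animal, session) pair, fits a Gaussian (maximum likelihood:
#' sample mean and standard deviation) to the pooled accelerometer readings
#' from the first 100 ms of every trial in the session. These readings always
#' precede the startle stimulus, so they characterise the resting signal and
#' the gain of the startle system.
#'
#' @param traces Long-format tibble of raw traces with columns `animal_id`,
#'   `session`, `trial`, `t_ms` (ms from trace start), `reading` (gain
#'   units) and `startle_onset_ms`.
#' @param window_ms Length of the pre-startle baseline window (default 100).
#' @return Tibble with one row per (animal, session): `mu`, `sigma`
#'   (gain units, sample SD) and `n_readings`.
#' @export
fit_session_baseline <- function(traces, window_ms = 100) {
  assert_cols(traces, c("animal_id", "session", "trial", "t_ms", "reading"),
              "trace table")
  pre <- dplyr::filter(traces, .data$t_ms < window_ms)
  out <- pre %>%
    group_by(.data$animal_id, .data$session) %>%
    summarise(mu = mean(.data$reading),
              sigma = sample_sd(.data$reading),
              n_readings = dplyr::n(), .groups = "drop")
  if (any(out$n_readings < 2)) {
    abort("Fewer than 2 pooled pre-startle readings in at least one session.",
          class = "ppiscale_insufficient_data")
  }
  if (any(out$sigma <= 0 | !is.finite(out$sigma))) {
    abort("Constant pre-startle signal: degenerate baseline (sigma = 0).",
          class = "ppiscale_degenerate_baseline")
  }
  out
}

#' z-score normalize accelerometer traces
#'
#' Subtracts the session baseline mean and divides by the session baseline
#' standard deviation, putting readings from startle systems with different
#' gains on a common scale.
#'
#' @inheritParams fit_session_baseline
#' @param baseline Output of [fit_session_baseline()] (or a tibble with
#'   `animal_id`, `session`, `mu`, `sigma`).
#' @return The trace tibble with `reading` replaced by its z-score; all other
#'   columns preserved.
#' @export
zscore_normalize <- function(traces, baseline) {
  assert_cols(baseline, c("animal_id", "session", "mu", "sigma"), "baseline table")
  if (any(baseline$sigma <= 0)) {
    abort("Invalid normalizer: sigma must be > 0.", class = "ppiscale_domain_error")
  }
  traces %>%
    left_join(baseline[, c("animal_id", "session", "mu", "sigma")],
              by = c("animal_id", "session")) %>%
    mutate(reading = (.data$reading - .data$mu) / .data$sigma) %>%
    select(-"mu", -"sigma")
}

#' Extract per-trial maximal startle from normalized traces
#'
#' Takes the maximal z-scored reading in the 100 ms following startle onset
#' as the trial's startle response, and its log10 as the trial's log
#' movement. Trials whose maximum is not positive have no defined log
#' movement; they are kept with `log_movement = NA` and flagged, and a
#' warning reports the dropped fraction.
#'
#' @param traces Normalized trace tibble (see [zscore_normalize()]) carrying
#'   stimulus columns `startle_db`, `prepulse_db`, `delay_ms` and
#'   `startle_onset_ms`.
#' @param window_ms Length of the post-onset search window (default 100).
#' @return Tibble with one row per trial: stimulus columns, `max_startle`
#'   (z units), `log_movement` (log10 z units) and `dropped` flag.
#' @export
extract_trial_movement <- function(traces, window_ms = 100) {
  assert_cols(traces,
              c("animal_id", "session", "trial", "t_ms", "reading",
                "startle_onset_ms", "startle_db", "prepulse_db", "delay_ms"),
              "trace table")
  out <- traces %>%
    filter(.data$t_ms >= .data$startle_onset_ms,
           .data$t_ms <= .data$startle_onset_ms + window_ms) %>%
    group_by(.data$animal_id, .data$session, .data$trial,
             .data$startle_db, .data$prepulse_db, .data$delay_ms) %>%
    summarise(max_startle = max(.data$reading), .groups = "drop") %>%
    mutate(dropped = .data$max_startle <= 0,
           log_movement = ifelse(.data$dropped, NA_real_,
                                 log10(pmax(.data$max_startle, .Machine$double.xmin))))
  if (any(out$dropped)) {
    warn(sprintf("%d of %d trials (%.1f%%) had non-positive maximal startle and were dropped from the log scale.",
                 sum(out$dropped), nrow(out), 100 * mean(out$dropped)))
  }
  out
}

#' Per-trial log movements from a trial table
#'
#' Converts a trial table with precomputed maximal startle readings
#' (`max_reading`, z-scored units) into trial movements on the log10 scale.
#' Habituation trials are excluded; non-positive readings are flagged and
#' excluded from the log scale with a warning, mirroring
#' [extract_trial_movement()].
#'
#' @param trials Trial table with columns `animal_id`, `startle_db`,
#'   `prepulse_db`, `delay_ms` and `max_reading` (plus optional `group`,
#'   `session`, `is_habituation`).
#' @return Tibble of usable trials with `log_movement` added.
#' @export
trial_movements <- function(trials) {
  assert_cols(trials, c("animal_id", "startle_db", "prepulse_db", "delay_ms",
                        "max_reading"), "trial table")
  if ("is_habituation" %in% names(trials)) {
    trials <- dplyr::filter(trials, !.data$is_habituation)
  }
  bad <- trials$max_reading <= 0
  if (any(bad)) {
    warn(sprintf("%d of %d trials (%.1f%%) had non-positive max readings and were dropped.",
                 sum(bad), length(bad), 100 * mean(bad)))
    trials <- trials[!bad, , drop = FALSE]
  }
  mutate(as_tibble(trials), log_movement = log10(.data$max_reading))
}

#' Summarise movement per animal and stimulus
#'
#' Averages per-trial log movements within each (animal, stimulus) cell,
#' pooling trial repeats across all sessions of an experiment. The mean of
#' the log movements is the "movement" of the animal to that stimulus; the
#' standard error uses the sample SD over trials.
#'
#' @param trials Tibble of trial movements (from [trial_movements()] or
#'   [extract_trial_movement()]) with a `log_movement` column.
#' @return Tibble with one row per animal x stimulus: `mean_log_movement`,
#'   `sem` and `n_trials`. Stimulus identity is (`startle_db`, `prepulse_db`,
#'   `delay_ms`); `group` and `condition_tag` are carried through if present.
#' @export
summarize_movement <- function(trials) {
  assert_cols(trials, c("animal_id", "startle_db", "prepulse_db", "delay_ms",
                        "log_movement"), "trial movement table")
  trials <- dplyr::filter(trials, !is.na(.data$log_movement))
  if (nrow(trials) == 0) {
    warn("No usable trials; returning an empty summary.")
  }
  keys <- intersect(c("animal_id", "group", "condition_tag",
                      "prepulse_db", "delay_ms", "startle_db"), names(trials))
  out <- trials %>%
    group_by(across(all_of(keys))) %>%
    summarise(mean_log_movement = mean(.data$log_movement),
              sem = sample_sd(.data$log_movement) / sqrt(dplyr::n()),
              n_trials = dplyr::n(), .groups = "drop")
  if (any(out$n_trials < 2)) {
    warn("Some (animal, stimulus) cells have fewer than 2 trials; their SEM is undefined.")
  }
  out
}

# Distribution screen for a single cell of positive trial maxima: Shapiro-Wilk
# p on the raw and log10 scales, and the log-likelihood advantage of a
# log-normal over a Gaussian at their respective maximum-likelihood parameters.
screen_values <- function(x) {
  if (length(x) < 3) {
    abort("Need at least 3 values for the distribution screen.",
          class = "ppiscale_insufficient_data")
  }
  if (any(x <= 0)) {
    abort("Non-positive values: log-normal branch undefined.",
          class = "ppiscale_domain_error")
  }
  n <- length(x)
  sd_mle <- function(v) sqrt(mean((v - mean(v))^2))
  ll_gauss <- sum(dnorm(x, mean(x), sd_mle(x), log = TRUE))
  lx <- log(x)
  ll_lnorm <- sum(dlnorm(x, mean(lx), sd_mle(lx), log = TRUE))
  c(p_raw = shapiro.test(x)$p.value,
    p_log = shapiro.test(log10(x))$p.value,
    loglik_diff = ll_lnorm - ll_gauss)
}

#' Screen the trial-noise distribution per animal and stimulus
#'
#' For every (animal, stimulus) cell, tests Gaussianity of the raw maximal
#' startle values and of their log10 transform (Shapiro-Wilk), and compares
#' log-normal against Gaussian fits by their maximised log-likelihood
#' difference (`loglik_diff > 0` means the log-normal is preferred). Cells
#' with fewer than 3 usable trials or with non-positive values are returned
#' with `NA` results and a `reason`.
#'
#' @param trials Trial table with `max_reading` (or `max_startle`) per trial.
#' @return Tibble with one row per animal x stimulus: `p_raw`, `p_log`,
#'   `loglik_diff`, `n_trials`, `reason`.
#' @export
distribution_screen <- function(trials) {
  if (!"max_reading" %in% names(trials) && "max_startle" %in% names(trials)) {
    trials <- rename(trials, max_reading = "max_startle")
  }
  assert_cols(trials, c("animal_id", "startle_db", "prepulse_db", "delay_ms",
                        "max_reading"), "trial table")
  if ("is_habituation" %in% names(trials)) {
    trials <- dplyr::filter(trials, !.data$is_habituation)
  }
  screen_cell <- function(x) {
    tryCatch(c(as.list(screen_values(x)), list(reason = NA_character_)),
             error = function(e) list(p_raw = NA_real_, p_log = NA_real_,
                                      loglik_diff = NA_real_,
                                      reason = conditionMessage(e)))
  }
  trials %>%
    group_by(.data$animal_id, .data$prepulse_db, .data$delay_ms,
             .data$startle_db) %>%
    summarise(res = list(screen_cell(.data$max_reading)),
              n_trials = dplyr::n(), .groups = "drop") %>%
    tidyr::unnest_wider("res")
}
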