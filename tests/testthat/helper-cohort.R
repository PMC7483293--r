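# Shared fixtures, built in code. Heavier objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Noiseless movement summaries for one animal with known parameters.
make_exact_summaries <- function(m_max = 2, r = 0.25, s0 = 30, m0 = 0.1,
                                 scalings = tibble::tibble(
                                   prepulse_db = c(6, 14), delay_ms = 100,
                                   alpha = c(0.9, 0.7), beta = c(0.95, 0.85)),
                                 baseline_levels = seq(0, 60, 10),
                                 condition_levels = seq(20, 60, 10),
                                 sem = 0.02, animal_id = "ex1") {
  base <- tibble::tibble(animal_id = animal_id, prepulse_db = 0, delay_ms = 0,
                         startle_db = baseline_levels, alpha = 1, beta = 1)
  cond <- tidyr::crossing(scalings, startle_db = condition_levels) |>
    dplyr::mutate(animal_id = animal_id)
  df <- dplyr::bind_rows(base, cond)
  df$mean_log_movement <- predicted_movement(df$startle_db, m_max, r, s0,
                                             alpha = df$alpha, beta = df$beta,
                                             m0 = m0)
  df$sem <- sem
  df$n_trials <- 60L
  df[, c("animal_id", "prepulse_db", "delay_ms", "startle_db",
         "mean_log_movement", "sem", "n_trials")]
}

# Small single-condition spec used by several tests.
small_spec <- function(trials_per_stimulus = 30, n_animals = 2, ...) {
  cohort_spec(n_animals = n_animals,
              conditions = tibble::tibble(prepulse_db = 14, delay_ms = 100,
                                          condition_tag = "prepulse"),
              trials_per_stimulus = trials_per_stimulus, ...)
}

# A cached 3-animal default-design cohort with summaries and fits.
small_cohort <- function() {
  cached("small_cohort", {
    co <- simulate_cohort(cohort_spec(n_animals = 3, trials_per_stimulus = 30),
                          seed = 101)
    tm <- trial_movements(co$trials)
    summ <- summarize_movement(tm)
    fits <- fit_cohort(summ)
    list(cohort = co, trials = tm, summaries = summ, fits = fits)
  })
}

# Feature tables drawn directly from the generative layer (no trial noise),
# for the group-analysis tests.
param_features <- function(spec, seed) {
  p <- sample_animal_params(spec, seed = seed)
  feats <- dplyr::left_join(
    p$scalings,
    dplyr::select(p$animals, "animal_id", "m_max", "r", "s0", "threshold"),
    by = "animal_id")
  feats$saturation <- feats$m_max
  feats
}

features_full <- function(feats) {
  feats[, c("animal_id", "group", "prepulse_db", "delay_ms",
            "m_max", "r", "s0", "alpha", "beta")]
}

features_reduced <- function(feats) {
  feats[, c("animal_id", "group", "prepulse_db", "delay_ms",
            "saturation", "threshold", "alpha", "beta")]
}
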