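#' Default prepulse-condition table
#'
#' Thirteen distinct (prepulse level, delay) conditions covering a
#' prepulse-varying family (six levels at a fixed 100 ms delay) and two
#' delay-varying families (delays 50-200 ms at 14 and 10 dB prepulse),
#' within the experimental ranges of 0-18 dB prepulse and 50-200 ms delay.
#'
#' @return Tibble with `prepulse_db`, `delay_ms`, `condition_tag`.
#' @export
default_conditions <- function() {
  bind_rows(
    tibble(prepulse_db = c(3, 6, 9, 12, 15, 18), delay_ms = 100,
           condition_tag = "prepulse"),
    tibble(prepulse_db = 14, delay_ms = c(50, 100, 150, 200),
           condition_tag = "delay"),
    tibble(prepulse_db = 10, delay_ms = c(50, 150, 200),
           condition_tag = "delay"))
}

# Mean scaling laws: scaling deepens with prepulse level and shortens with
# delay. effect in [0, ~1.3]; alpha drops up to ~0.45 of its range, beta up
# to ~0.2, at the strongest condition.
scaling_effect <- function(prepulse_db, delay_ms) {
  (prepulse_db / 18) * pmax((250 - delay_ms) / 150, 0)
}

#' Specification of a synthetic startle cohort
#'
#' Describes the generative model for a cohort of simulated animals: group
#' sizes, animal-level distributions of the baseline curve parameters,
#' per-condition scaling laws, correlation targets between scaling and
#' baseline parameters, trial counts and log-scale trial noise. Defaults
#' emulate a 12-session experiment with 60 repeats per stimulus, startle
#' levels 0-60 dB above background and log10 trial noise of SD 0.15.
#'
#' Animal-level parameters are drawn from a latent Gaussian with the
#' requested correlations between (alpha, m_max) and (beta, s0); because the
#' threshold also inherits independent slope variation, the realized
#' correlation with the threshold is attenuated slightly below
#' `rho_beta_threshold`.
#'
#' @param groups Tibble with `label` and `n` per group.
#' @param n_animals Shorthand for a single-group cohort of this size.
#' @param conditions Condition table (`prepulse_db`, `delay_ms`,
#'   `condition_tag`); see [default_conditions()].
#' @param baseline_levels Startle levels (dB) for the no-prepulse condition.
#' @param condition_levels Startle levels paired with each prepulse condition.
#' @param m_max_mean,m_max_sd,r_mean,r_sd,s0_mean,s0_sd,m0_mean,m0_sd
#'   Animal-level distribution of the baseline curve parameters.
#' @param alpha_max_drop,beta_max_drop Depth of the mean scaling at the
#'   strongest condition (18 dB prepulse, 100 ms delay).
#' @param alpha_mean,beta_mean Optional overrides: a single value (all
#'   conditions) or one value per condition, replacing the scaling laws.
#' @param alpha_sd,beta_sd Animal-level SD of the scaling parameters.
#' @param alpha_condition_sd,beta_condition_sd Independent per-condition
#'   jitter of the scaling parameters.
#' @param rho_alpha_mmax,rho_beta_threshold Correlation targets between the
#'   latent scaling and baseline draws.
#' @param rho_alpha_beta Optional correlation between the two scaling
#'   latents.
#' @param group_offsets Named list: group label -> named numeric vector of
#'   additive offsets on any of `m_max`, `r`, `s0`, `m0`, `alpha`, `beta`.
#' @param trials_per_stimulus Trial repeats per stimulus (median design: 60).
#' @param sigma SD of per-trial log10 movement around the model mean.
#' @param n_sessions Sessions per experiment (trials spread round-robin).
#' @param habituation_trials Habituation trials per session (50 dB startle,
#'   no prepulse), flagged and excluded by the preprocessing.
#' @param seed Default seed for [simulate_cohort()].
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups = NULL, n_animals = 20,
                        conditions = default_conditions(),
                        baseline_levels = seq(0, 60, 10),
                        condition_levels = seq(20, 60, 10),
                        m_max_mean = 2, m_max_sd = 0.35,
                        r_mean = 0.25, r_sd = 0.04,
                        s0_mean = 30, s0_sd = 4,
                        m0_mean = 0.1, m0_sd = 0.03,
                        alpha_max_drop = 0.45, beta_max_drop = 0.2,
                        alpha_mean = NULL, beta_mean = NULL,
                        alpha_sd = 0.08, beta_sd = 0.05,
                        alpha_condition_sd = 0.02, beta_condition_sd = 0.01,
                        rho_alpha_mmax = -0.5, rho_beta_threshold = -0.65,
                        rho_alpha_beta = 0,
                        group_offsets = list(),
                        trials_per_stimulus = 60, sigma = 0.15,
                        n_sessions = 12, habituation_trials = 5,
                        seed = NULL) {
  if (is.null(groups)) groups <- tibble(label = "wt", n = n_animals)
  assert_cols(groups, c("label", "n"), "groups")
  stopifnot(all(groups$n >= 1), trials_per_stimulus >= 1, sigma >= 0,
            all(c(m_max_sd, r_sd, s0_sd, m0_sd, alpha_sd, beta_sd) >= 0),
            all(abs(c(rho_alpha_mmax, rho_beta_threshold, rho_alpha_beta)) <= 1))
  conditions <- as_tibble(conditions)
  assert_cols(conditions, c("prepulse_db", "delay_ms"), "condition table")
  if (!"condition_tag" %in% names(conditions)) conditions$condition_tag <- "prepulse"
  eff <- scaling_effect(conditions$prepulse_db, conditions$delay_ms)
  conditions$alpha_mean <- if (is.null(alpha_mean)) {
    pmax(1 - alpha_max_drop * eff, 0.05)
  } else rep_len(alpha_mean, nrow(conditions))
  conditions$beta_mean <- if (is.null(beta_mean)) {
    pmax(1 - beta_max_drop * eff, 0.05)
  } else rep_len(beta_mean, nrow(conditions))
  spec <- list(groups = groups, conditions = conditions,
               baseline_levels = baseline_levels,
               condition_levels = condition_levels,
               m_max_mean = m_max_mean, m_max_sd = m_max_sd,
               r_mean = r_mean, r_sd = r_sd, s0_mean = s0_mean, s0_sd = s0_sd,
               m0_mean = m0_mean, m0_sd = m0_sd,
               alpha_sd = alpha_sd, beta_sd = beta_sd,
               alpha_condition_sd = alpha_condition_sd,
               beta_condition_sd = beta_condition_sd,
               rho_alpha_mmax = rho_alpha_mmax,
               rho_beta_threshold = rho_beta_threshold,
               rho_alpha_beta = rho_alpha_beta,
               group_offsets = group_offsets,
               trials_per_stimulus = trials_per_stimulus, sigma = sigma,
               n_sessions = n_sessions, habituation_trials = habituation_trials,
               seed = seed)
  structure(spec, class = "cohort_spec")
}

# Latent correlation matrix over (z_mmax, z_s0, z_alpha, z_beta).
latent_corr <- function(spec) {
  R <- diag(4)
  dimnames(R) <- list(c("mmax", "s0", "alpha", "beta"),
                      c("mmax", "s0", "alpha", "beta"))
  R["mmax", "alpha"] <- R["alpha", "mmax"] <- spec$rho_alpha_mmax
  R["s0", "beta"] <- R["beta", "s0"] <- spec$rho_beta_threshold
  R["alpha", "beta"] <- R["beta", "alpha"] <- spec$rho_alpha_beta
  R
}

#' Draw true per-animal parameters for a synthetic cohort
#'
#' Samples jointly distributed baseline and scaling parameters: a 4-d latent
#' Gaussian (saturation, midpoint, startle-scaling and sound-scaling
#' components) with the cohort spec's correlation structure is mapped through the
#' animal-level means/SDs, scaling values are clamped into (0, 1\] and group
#' offsets applied afterwards. Slope `r` and floor `m0` are drawn
#' independently.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed.
#' @return List with `animals` (one row per animal: group and baseline
#'   parameters, plus the latent scaling draws) and `scalings` (one row per
#'   animal x condition: true `alpha`, `beta`).
#' @export
sample_animal_params <- function(spec, seed = spec$seed) {
  R <- latent_corr(spec)
  L <- tryCatch(chol(R), error = function(e) {
    abort("Infeasible correlation structure: latent correlation matrix is not positive definite.",
          class = "ppiscale_spec_error")
  })
  n_total <- sum(spec$groups$n)
  group_of <- rep(spec$groups$label, spec$groups$n)
  with_seed_if(seed, {
    Z <- matrix(rnorm(n_total * 4), n_total, 4) %*% L
    colnames(Z) <- colnames(R)
    offs <- function(g, par) {
      o <- spec$group_offsets[[g]]
      if (is.null(o) || is.na(o[par])) 0 else unname(o[par])
    }
    off_vec <- function(par) unname(vapply(group_of, offs, numeric(1), par = par))
    animals <- tibble(
      animal_id = sprintf("a%02d", seq_len(n_total)),
      group = group_of,
      m_max = pmax(spec$m_max_mean + spec$m_max_sd * Z[, "mmax"] +
                     off_vec("m_max"), 0.2),
      r = pmax(spec$r_mean + spec$r_sd * rnorm(n_total) + off_vec("r"), 0.05),
      s0 = spec$s0_mean + spec$s0_sd * Z[, "s0"] + off_vec("s0"),
      m0 = pmax(spec$m0_mean + spec$m0_sd * rnorm(n_total) + off_vec("m0"), 0),
      z_alpha = Z[, "alpha"], z_beta = Z[, "beta"])
    animals$threshold <- baseline_threshold(animals$r, animals$s0)
    scalings <- tidyr::crossing(animal_id = animals$animal_id,
                                spec$conditions[, c("prepulse_db", "delay_ms",
                                                    "condition_tag",
                                                    "alpha_mean", "beta_mean")]) %>%
      left_join(animals[, c("animal_id", "group", "z_alpha", "z_beta")],
                by = "animal_id") %>%
      mutate(
        alpha = pmin(pmax(.data$alpha_mean + spec$alpha_sd * .data$z_alpha +
                            spec$alpha_condition_sd * rnorm(dplyr::n()) +
                            off_vec("alpha")[match(.data$animal_id, animals$animal_id)],
                          0.01), 1),
        beta = pmin(pmax(.data$beta_mean + spec$beta_sd * .data$z_beta +
                           spec$beta_condition_sd * rnorm(dplyr::n()) +
                           off_vec("beta")[match(.data$animal_id, animals$animal_id)],
                         0.01), 1)) %>%
      select("animal_id", "group", "condition_tag", "prepulse_db", "delay_ms",
             "alpha", "beta")
    list(animals = animals, scalings = scalings)
  })
}

#' Simulate a trial table from true parameters
#'
#' Generates per-trial maximal startle readings with log-normal trial noise:
#' each trial's log10 movement is drawn from a Gaussian centred on the model
#' mean `m0 + alpha_c N(beta_c s)` with SD `sigma`, and the stored
#' `max_reading` is `10^draw` (z-scored units). The stimulus set pairs the
#' baseline condition with `baseline_levels` (including 0 dB, which anchors
#' the floor `m0`) and every prepulse condition with `condition_levels`.
#' Trials are spread round-robin over sessions, and each session gets
#' flagged habituation trials.
#'
#' @param params Output of [sample_animal_params()].
#' @param spec The same [cohort_spec()].
#' @param seed RNG seed.
#' @return Trial table matching the package's input schema: `animal_id`,
#'   `group`, `session`, `trial`, `startle_db`, `prepulse_db`, `delay_ms`,
#'   `condition_tag`, `is_habituation`, `max_reading`.
#' @export
simulate_trials <- function(params, spec, seed = spec$seed) {
  stim <- bind_rows(
    tibble(prepulse_db = 0, delay_ms = 0, condition_tag = "baseline",
           startle_db = spec$baseline_levels, alpha = 1, beta = 1),
    tidyr::crossing(spec$conditions[, c("prepulse_db", "delay_ms", "condition_tag")],
                    startle_db = spec$condition_levels))
  with_seed_if(seed, {
    purrr::map(seq_len(nrow(params$animals)), function(i) {
      an <- params$animals[i, ]
      sc <- filter(params$scalings, .data$animal_id == an$animal_id)
      st <- stim %>%
        left_join(sc[, c("prepulse_db", "delay_ms", "alpha", "beta")],
                  by = c("prepulse_db", "delay_ms")) %>%
        mutate(alpha = dplyr::coalesce(.data$alpha.y, .data$alpha.x),
               beta = dplyr::coalesce(.data$beta.y, .data$beta.x)) %>%
        select(-dplyr::any_of(c("alpha.x", "alpha.y", "beta.x", "beta.y")))
      st$mu <- predicted_movement(st$startle_db, an$m_max, an$r, an$s0,
                                  alpha = st$alpha, beta = st$beta, m0 = an$m0)
      n_rep <- spec$trials_per_stimulus
      trials <- st[rep(seq_len(nrow(st)), each = n_rep), ] %>%
        mutate(animal_id = an$animal_id, group = an$group,
               rep_idx = rep(seq_len(n_rep), times = nrow(st)),
               session = ((.data$rep_idx - 1L) %% spec$n_sessions) + 1L,
               is_habituation = FALSE,
               log_m = rnorm(dplyr::n(), .data$mu, spec$sigma))
      hab_mu <- predicted_movement(50, an$m_max, an$r, an$s0, m0 = an$m0)
      hab <- tibble(animal_id = an$animal_id, group = an$group,
                    session = rep(seq_len(spec$n_sessions),
                                  each = spec$habituation_trials),
                    startle_db = 50, prepulse_db = 0, delay_ms = 0,
                    condition_tag = "baseline", is_habituation = TRUE,
                    log_m = rnorm(spec$n_sessions * spec$habituation_trials,
                                  hab_mu, spec$sigma))
      bind_rows(trials, hab) %>%
        arrange(.data$session) %>%
        group_by(.data$session) %>%
        mutate(trial = row_number()) %>%
        ungroup() %>%
        mutate(max_reading = 10^.data$log_m) %>%
        select("animal_id", "group", "session", "trial", "startle_db",
               "prepulse_db", "delay_ms", "condition_tag", "is_habituation",
               "max_reading")
    }) %>% bind_rows()
  })
}

#' Simulate a complete synthetic cohort
#'
#' Draws true animal parameters and the corresponding trial table in one
#' call with deterministic sub-seeding: the same spec and seed always
#' reproduce the identical dataset.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return List of class `"ppi_cohort"`: `params` (true parameters) and
#'   `trials` (trial table).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  seeds <- child_seeds(if (is.null(seed)) sample.int(2^31 - 1, 1) else seed, 2)
  params <- sample_animal_params(spec, seed = seeds[[1]])
  trials <- simulate_trials(params, spec, seed = seeds[[2]])
  structure(list(params = params, trials = trials, spec = spec),
            class = "ppi_cohort")
}

#' @export
print.ppi_cohort <- function(x, ...) {
  cat(sprintf("<ppi_cohort> %d animals, %d conditions, %d trials\n",
              nrow(x$params$animals), nrow(x$spec$conditions), nrow(x$trials)))
  invisible(x)
}

#' Simulate raw accelerometer traces for a trial table
#'
#' Produces stylized traces whose preprocessing round-trips to the trial
#' table's intended maximal startle: each trace has a Gaussian pre-startle
#' baseline (per-session gain `mu`, `sigma`) for 100 ms, followed by a
#' noise-free half-sine startle transient in the 100 ms after onset whose
#' peak equals `mu + sigma * max_reading`, so that z-scoring with the fitted
#' session baseline recovers `max_reading` up to baseline-estimation error.
#'
#' @param trials Trial table (see [simulate_trials()]).
#' @param sample_rate_hz Samples per second (default 1000).
#' @param gain_mu,gain_sigma Per-session baseline mean and SD in gain units.
#' @param seed RNG seed.
#' @return Long trace tibble: identifying columns, `t_ms`, `reading`,
#'   `startle_onset_ms`.
#' @export
simulate_traces <- function(trials, sample_rate_hz = 1000,
                            gain_mu = 50, gain_sigma = 8, seed = NULL) {
  stopifnot(sample_rate_hz > 0)
  n_pre <- round(0.1 * sample_rate_hz)
  n_post <- round(0.1 * sample_rate_hz)
  shape <- sin(pi * seq_len(n_post) / (n_post + 1))
  shape <- shape / max(shape)
  with_seed_if(seed, {
    purrr::map(seq_len(nrow(trials)), function(i) {
      tr <- trials[i, ]
      pre <- rnorm(n_pre, gain_mu, gain_sigma)
      post <- gain_mu + gain_sigma * tr$max_reading * shape
      tibble(animal_id = tr$animal_id, session = tr$session, trial = tr$trial,
             startle_db = tr$startle_db, prepulse_db = tr$prepulse_db,
             delay_ms = tr$delay_ms,
             t_ms = (seq_len(n_pre + n_post) - 1) / sample_rate_hz * 1000,
             reading = c(pre, post),
             startle_onset_ms = n_pre / sample_rate_hz * 1000)
    }) %>% bind_rows()
  })
}
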