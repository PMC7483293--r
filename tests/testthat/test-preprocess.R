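make_traces <- function(readings_by_trial, onset = 100, dt = 1,
                        animal = "a1", session = 1L) {
  purrr::imap(readings_by_trial, function(v, i) {
    tibble::tibble(animal_id = animal, session = session, trial = i,
                   startle_db = 40, prepulse_db = 0, delay_ms = 0,
                   t_ms = (seq_along(v) - 1) * dt, reading = v,
                   startle_onset_ms = onset)
  }) |> dplyr::bind_rows()
}

test_that("session baseline recovers the generating Gaussian and matches direct estimators", {
  set.seed(41)
  vals <- rnorm(10000, 5, 2)
  tr <- make_traces(list(vals), onset = 150)
  tr$t_ms <- rep_len(seq(0, 99.99, length.out = 100), nrow(tr)) # all pre-startle
  bl <- fit_session_baseline(tr)
  expect_equal(bl$mu, mean(vals), tolerance = 1e-12)
  expect_equal(bl$sigma, sd(vals), tolerance = 1e-12)
  expect_lt(abs(bl$mu - 5), 3 * 2 / sqrt(10000))
  expect_lt(abs(bl$sigma - 2), 3 * 2 / sqrt(2 * 10000))
})

test_that("degenerate and tiny baselines are handled per the conventions", {
  tr_const <- make_traces(list(rep(3, 50)))
  tr_const$t_ms <- seq(0, 98, 2)
  expect_error(fit_session_baseline(tr_const), class = "ppiscale_degenerate_baseline")

  tr2 <- make_traces(list(c(0, 2)))
  tr2$t_ms <- c(0, 50)
  bl <- fit_session_baseline(tr2)
  expect_equal(bl$mu, 1)
  expect_equal(bl$sigma, sqrt(2)) # sample (n-1) SD convention
})

test_that("z-score normalization is exact and idempotent", {
  bl <- tibble::tibble(animal_id = "a1", session = 1L, mu = 5, sigma = 2)
  tr <- make_traces(list(c(5, 5, 5), 7))
  tr$t_ms <- c(0, 10, 20, 0)
  z <- zscore_normalize(tr, bl)
  expect_equal(z$reading, c(0, 0, 0, 1))

  # refit on normalized readings gives mu ~ 0, sigma ~ 1; renormalizing is a no-op
  set.seed(7)
  tr_big <- make_traces(list(rnorm(500, 10, 3)))
  tr_big$t_ms <- rep_len(seq(0, 99, 1), nrow(tr_big))
  z1 <- zscore_normalize(tr_big, fit_session_baseline(tr_big))
  bl1 <- fit_session_baseline(z1)
  expect_equal(bl1$mu, 0, tolerance = 1e-12)
  expect_equal(bl1$sigma, 1, tolerance = 1e-12)
  z2 <- zscore_normalize(z1, bl1)
  expect_equal(z2$reading, z1$reading, tolerance = 1e-6)

  expect_error(zscore_normalize(tr, dplyr::mutate(bl, sigma = 0)),
               class = "ppiscale_domain_error")
})

test_that("trial movement extraction takes the post-onset window maximum on the log10 scale", {
  tr <- make_traces(list(c(rep(0.5, 3), 0.1, 3.0, 1.2),
                         c(rep(0.5, 3), -1, -0.2, -3),
                         c(rep(0.5, 3), 0.2, 1, 0.5)),
                    onset = 30, dt = 10)
  expect_warning(mv <- extract_trial_movement(tr), "non-positive")
  mv <- dplyr::arrange(mv, trial)
  expect_equal(mv$max_startle, c(3, -0.2, 1))
  expect_equal(mv$log_movement[1], log10(3), tolerance = 1e-12)
  expect_true(mv$dropped[2] && is.na(mv$log_movement[2]))
  expect_equal(mv$log_movement[3], 0)
})

test_that("movement summaries equal brute-force means and SEMs", {
  tr <- tibble::tibble(animal_id = "a1", startle_db = 40, prepulse_db = 0,
                       delay_ms = 0, log_movement = c(0, 1))
  s <- suppressWarnings(summarize_movement(tr))
  expect_equal(s$mean_log_movement, 0.5)
  expect_equal(s$sem, 0.5)

  tr2 <- dplyr::mutate(tr[rep(1, 60), ], log_movement = 0.3)
  s2 <- summarize_movement(tr2)
  expect_equal(s2$mean_log_movement, 0.3)
  expect_equal(s2$sem, 0)
  expect_equal(s2$n_trials, 60L)

  # brute-force oracle on arbitrary input
  set.seed(11)
  tr3 <- tibble::tibble(animal_id = rep(c("a1", "a2"), each = 50),
                        startle_db = rep(c(30, 50), 50), prepulse_db = 6,
                        delay_ms = 100, log_movement = rnorm(100, 1, 0.4))
  s3 <- summarize_movement(tr3)
  for (i in seq_len(nrow(s3))) {
    v <- tr3$log_movement[tr3$animal_id == s3$animal_id[i] &
                            tr3$startle_db == s3$startle_db[i]]
    expect_equal(s3$mean_log_movement[i], sum(v) / length(v), tolerance = 1e-12)
    expect_equal(s3$sem[i], sd(v) / sqrt(length(v)), tolerance = 1e-12)
  }

  # sampling check: mean of 60 draws within 4 sigma/sqrt(60)
  set.seed(12)
  tr4 <- tibble::tibble(animal_id = "a1", startle_db = 40, prepulse_db = 0,
                        delay_ms = 0, log_movement = rnorm(60, 1.2, 0.15))
  expect_lt(abs(summarize_movement(tr4)$mean_log_movement - 1.2),
            4 * 0.15 / sqrt(60))
})

test_that("habituation trials are excluded from movement summaries", {
  tr <- tibble::tibble(animal_id = "a1", startle_db = 50, prepulse_db = 0,
                       delay_ms = 0, max_reading = c(rep(10, 20), rep(1000, 5)),
                       is_habituation = rep(c(FALSE, TRUE), c(20, 5)))
  s <- summarize_movement(trial_movements(tr))
  expect_equal(s$n_trials, 20L)
  expect_equal(s$mean_log_movement, 1)
})

test_that("distribution screen prefers the log-normal for log-normal data", {
  set.seed(21)
  x <- exp(rnorm(500))
  res <- ppiscale:::screen_values(x)
  expect_gt(res[["loglik_diff"]], 0)
  expect_gt(res[["p_log"]], res[["p_raw"]])

  # nearly Gaussian far from zero: no strong preference, raw p large
  y <- abs(rnorm(500, 10, 0.1))
  res2 <- ppiscale:::screen_values(y)
  expect_lt(abs(res2[["loglik_diff"]]), 5)
  expect_gt(res2[["p_raw"]], 0.01)

  expect_error(ppiscale:::screen_values(c(1, 2, 0)), class = "ppiscale_domain_error")
  expect_error(ppiscale:::screen_values(c(1, 2)), class = "ppiscale_insufficient_data")
})

test_that("distribution_screen reports per-cell results and reasons", {
  set.seed(22)
  trials <- tibble::tibble(
    animal_id = rep(c("a1", "a1", "a2"), each = 30),
    startle_db = rep(c(30, 50, 30), each = 30),
    prepulse_db = 0, delay_ms = 0,
    max_reading = c(10^rnorm(60, 1, 0.2), c(-1, 10^rnorm(29, 1, 0.2))))
  scr <- distribution_screen(trials)
  expect_equal(nrow(scr), 3L)
  ok <- scr[!is.na(scr$p_raw), ]
  expect_true(all(ok$loglik_diff > -5))
  bad <- scr[is.na(scr$p_raw), ]
  expect_equal(nrow(bad), 1L)
  expect_match(bad$reason, "Non-positive")
})
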