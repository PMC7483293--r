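#' Baseline-adjusted group comparison of scaling parameters (ANCOVA)
#'
#' Because startle scaling covaries with baseline saturation and sound
#' scaling with baseline threshold, group differences in the scaling
#' parameters are tested with the baseline feature as a covariate. Per
#' condition and response the procedure is:
#' \enumerate{
#'   \item Check the groups for a difference in the covariate itself
#'     (two-sample t-test). ANCOVA is inappropriate under nonrandom group
#'     differences in the covariate, so such conditions are excluded with
#'     the reason recorded.
#'   \item Fit `response ~ covariate * group` and test the interaction
#'     (homogeneity of slopes). If the interaction is significant the
#'     stage halts: no common-slope group effect is reported.
#'   \item Otherwise refit without the interaction and report the group
#'     main-effect p-value and the common slope.
#' }
#'
#' @param features Reduced feature table for two groups across conditions.
#' @param responses Which scaling parameters to test (default both).
#' @param alpha_level Significance level for the covariate screen and the
#'   interaction check.
#' @return Tibble with one row per condition x response: covariate used,
#'   `covariate_p` (group difference in covariate), `interaction_p`,
#'   `group_p`, per-group slopes, `excluded` flag and `reason`.
#' @export
ancova_scaling <- function(features, responses = c("alpha", "beta"),
                           alpha_level = 0.05) {
  assert_cols(features, c("animal_id", "group", "prepulse_db", "delay_ms",
                          "saturation", "threshold", "alpha", "beta"),
              "reduced feature table")
  covariate_for <- c(alpha = "saturation", beta = "threshold")
  grp_keys <- intersect(c("condition_tag", "prepulse_db", "delay_ms"),
                        names(features))
  one <- function(d, resp) {
    cov_col <- covariate_for[[resp]]
    base <- tibble(response = resp, covariate = cov_col,
                   covariate_p = NA_real_, interaction_p = NA_real_,
                   group_p = NA_real_, slope_1 = NA_real_, slope_2 = NA_real_,
                   common_slope = NA_real_, excluded = FALSE,
                   reason = NA_character_)
    groups <- sort(unique(d$group))
    if (length(groups) != 2 || any(table(d$group) < 3)) {
      base$excluded <- TRUE; base$reason <- "needs >= 3 animals in each of 2 groups"
      return(base)
    }
    if (sample_sd(d[[cov_col]]) == 0) {
      base$excluded <- TRUE; base$reason <- "zero covariate variance"
      return(base)
    }
    dd <- tibble(y = d[[resp]], x = d[[cov_col]],
                 g = factor(d$group, levels = groups))
    base$covariate_p <- t.test(x ~ g, data = dd)$p.value
    if (base$covariate_p < alpha_level) {
      base$excluded <- TRUE
      base$reason <- "group difference in baseline covariate"
      return(base)
    }
    m_int <- lm(y ~ x * g, data = dd)
    if (anyNA(coef(m_int))) {
      base$excluded <- TRUE; base$reason <- "inestimable model (collinearity)"
      return(base)
    }
    a_int <- anova(m_int)
    base$interaction_p <- a_int["x:g", "Pr(>F)"]
    cf <- coef(m_int)
    base$slope_1 <- unname(cf["x"])
    base$slope_2 <- unname(cf["x"] + cf[grep("^x:g", names(cf))])
    if (base$interaction_p <= alpha_level) {
      base$reason <- "heterogeneous slopes: group effect not reported"
      return(base)
    }
    m_add <- lm(y ~ x + g, data = dd)
    base$group_p <- anova(m_add)["g", "Pr(>F)"]
    base$common_slope <- unname(coef(m_add)["x"])
    base
  }
  features %>%
    group_by(across(all_of(grp_keys))) %>%
    dplyr::group_modify(function(d, key) {
      bind_rows(lapply(intersect(responses, c("alpha", "beta")),
                       function(r) one(d, r)))
    }) %>%
    ungroup()
}

#' Slopes of the scaling parameters against the stimulus dimension
#'
#' For each animal, regresses the startle scaling and the sound scaling on
#' the varied stimulus dimension (prepulse sound level, or delay) across
#' that animal's conditions, then tests whether the population of per-animal
#' slopes has nonzero mean (one-sample t-test). Greater prepulse sounds and
#' shorter delays are expected to produce greater scaling (smaller alpha,
#' beta), i.e. negative slopes against prepulse level and positive slopes
#' against delay.
#'
#' @param fits Cohort fit table from [fit_cohort()].
#' @param vary `"prepulse"` (slopes against `prepulse_db`) or `"delay"`
#'   (against `delay_ms`). When the feature table has a `condition_tag`
#'   column only conditions with the matching tag are used.
#' @return List with `slopes` (tibble: animal, parameter, slope, n
#'   conditions) and `tests` (one-sample t-test per parameter). Animals with
#'   fewer than 3 usable conditions are skipped with a warning.
#' @export
scaling_vs_stimulus_slopes <- function(fits, vary = c("prepulse", "delay")) {
  vary <- match.arg(vary)
  xcol <- if (vary == "prepulse") "prepulse_db" else "delay_ms"
  feats <- condition_features(fits, "full")
  if ("condition_tag" %in% names(feats)) {
    feats <- filter(feats, .data$condition_tag == vary)
  }
  n_skipped <- 0
  slopes <- feats %>%
    dplyr::group_split(.data$animal_id) %>%
    purrr::map(function(d) {
      if (dplyr::n_distinct(d[[xcol]]) < 3) {
        n_skipped <<- n_skipped + 1
        return(NULL)
      }
      tibble(animal_id = d$animal_id[[1]],
             group = if ("group" %in% names(d)) d$group[[1]] else NA_character_,
             parameter = c("alpha", "beta"),
             slope = c(ols_slope(d[[xcol]], d$alpha),
                       ols_slope(d[[xcol]], d$beta)),
             n_conditions = nrow(d))
    }) %>% bind_rows()
  if (n_skipped > 0) {
    warn(sprintf("%d animals skipped (< 3 conditions varying %s).", n_skipped, vary))
  }
  if (nrow(slopes) == 0) {
    return(list(slopes = tibble(animal_id = character(), group = character(),
                                parameter = character(), slope = numeric(),
                                n_conditions = integer()),
                tests = tibble(parameter = character(), mean_slope = numeric(),
                               t_statistic = numeric(), p_value = numeric(),
                               n_animals = integer()),
                vary = vary))
  }
  tests <- slopes %>%
    group_by(.data$parameter) %>%
    summarise(mean_slope = mean(.data$slope),
              t_statistic = if (dplyr::n() >= 2 && sample_sd(.data$slope) > 0)
                t.test(.data$slope)$statistic else NA_real_,
              p_value = if (dplyr::n() >= 2 && sample_sd(.data$slope) > 0)
                t.test(.data$slope)$p.value else NA_real_,
              n_animals = dplyr::n(), .groups = "drop")
  list(slopes = slopes, tests = tests, vary = vary)
}
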