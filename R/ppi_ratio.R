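#' Traditional PPI ratio
#'
#' The standard prepulse-inhibition metric at a single startle sound level:
#' `1 - m_p / m_b`, where `m_b` is the movement to the startle sound alone
#' and `m_p` the movement when the startle sound is preceded by a prepulse.
#' Here movements are the per-stimulus mean log movements, so values near
#' threshold can be negative; a negative `m_b` makes the ratio hard to
#' interpret and triggers a warning.
#'
#' @param m_b Baseline (no-prepulse) movement(s); must be nonzero.
#' @param m_p Prepulse-condition movement(s).
#' @return `1 - m_p / m_b`, at most 1; negative values indicate facilitation.
#' @examples
#' ppi_ratio(2, 1) # 0.5
#' @export
ppi_ratio <- function(m_b, m_p) {
  if (any(m_b == 0)) {
    abort("PPI ratio undefined for zero baseline movement.",
          class = "ppiscale_domain_error")
  }
  if (any(m_b < 0)) {
    warn("Negative baseline movement(s): PPI ratio is ill-defined near the startle floor.")
  }
  1 - m_p / m_b
}

#' PPI ratio table from movement summaries
#'
#' Pairs every prepulse-condition summary with the matching no-prepulse
#' summary from the same animal at the same startle sound level and computes
#' the PPI ratio from the mean log movements. Records with a non-positive
#' baseline movement are kept but flagged.
#'
#' @param summaries Movement summaries (see [summarize_movement()]).
#' @return Tibble with one row per animal x condition x startle level:
#'   `m_b`, `m_p`, `ppi_ratio`, `flagged_baseline`.
#' @export
ppi_ratio_table <- function(summaries) {
  assert_cols(summaries, c("animal_id", "prepulse_db", "delay_ms",
                           "startle_db", "mean_log_movement"), "summary table")
  base <- summaries %>%
    filter(is_baseline_condition(.data$prepulse_db)) %>%
    select("animal_id", "startle_db", m_b = "mean_log_movement")
  pp <- filter(summaries, !is_baseline_condition(.data$prepulse_db))
  out <- pp %>%
    dplyr::inner_join(base, by = c("animal_id", "startle_db")) %>%
    rename(m_p = "mean_log_movement")
  n_unmatched <- nrow(pp) - nrow(out)
  if (n_unmatched > 0) {
    warn(sprintf("%d prepulse summaries had no matching same-level baseline and were skipped.",
                 n_unmatched))
  }
  if (any(out$m_b == 0)) {
    out <- filter(out, .data$m_b != 0)
    warn("Records with zero baseline movement were removed (undefined ratio).")
  }
  out %>%
    mutate(ppi_ratio = 1 - .data$m_p / .data$m_b,
           flagged_baseline = .data$m_b <= 0) %>%
    select(dplyr::any_of(c("animal_id", "group", "condition_tag")),
           "prepulse_db", "delay_ms", "startle_db", "m_b", "m_p",
           "ppi_ratio", "flagged_baseline")
}

# Closed-form OLS slope of y on x.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Per-condition slopes of PPI ratio versus startle sound level
#'
#' For each animal and prepulse condition, fits an ordinary least-squares
#' regression of the PPI ratio on startle sound level. If prepulse inhibition
#' were a pure scaling of the startle response, these slopes could not be
#' negative; systematically negative slopes are the signature of an
#' additional scaling along the sound axis.
#'
#' @param summaries Movement summaries (see [summarize_movement()]), spanning
#'   at least two startle levels with matched baselines per condition.
#' @return Tibble with one row per animal x condition: `slope` (per dB) and
#'   `n_levels`.
#' @export
ppi_ratio_slopes <- function(summaries) {
  ratios <- ppi_ratio_table(summaries)
  out <- ratios %>%
    group_by(across(all_of(intersect(c("animal_id", "group", "condition_tag",
                                       "prepulse_db", "delay_ms"),
                                     names(ratios))))) %>%
    summarise(n_levels = dplyr::n(),
              slope = if (dplyr::n() >= 2) ols_slope(.data$startle_db, .data$ppi_ratio)
                      else NA_real_,
              .groups = "drop")
  if (any(is.na(out$slope))) {
    warn("Conditions with fewer than 2 matched startle levels were skipped.")
    out <- filter(out, !is.na(.data$slope))
  }
  out
}

#' Theoretical PPI ratio under the startle-scaling-only model
#'
#' Under a pure startle scaling of the baseline curve
#' (`m_p = m0 + alpha * N(s)`, `m_b = m0 + N(s)`), the PPI ratio is
#' `1 - (m0 + alpha N(s)) / (m0 + N(s))`, which is non-decreasing in the
#' startle sound level whenever `m0 >= 0` and `0 < alpha <= 1`. The observed
#' systematic decrease of the PPI ratio with sound level therefore rules out
#' a pure startle scaling.
#'
#' @inheritParams startle_sigmoid
#' @param alpha Startle scaling, in (0, 1].
#' @param m0 Sound-independent floor, must be >= 0.
#' @return Theoretical PPI ratio at each `s`.
#' @export
theoretical_ppi_ratio <- function(s, alpha, m_max, r, s0, m0 = 0) {
  if (m0 < 0 || alpha <= 0 || alpha > 1 || m_max <= 0 || r <= 0) {
    abort("Require m0 >= 0, 0 < alpha <= 1 and a valid sigmoid (m_max > 0, r > 0).",
          class = "ppiscale_domain_error")
  }
  n_s <- startle_sigmoid(s, m_max, r, s0)
  1 - (m0 + alpha * n_s) / (m0 + n_s)
}
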