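#' Per-condition feature vectors from cohort fits
#'
#' Builds the per-animal, per-condition feature tables used by the group
#' analyses. The `"full"` set carries the raw five model parameters
#' (`m_max`, `r`, `s0`, `alpha`, `beta`) used for linear discriminant
#' analysis; the `"reduced"` set replaces the two sound-axis baseline
#' parameters by the single interpretable `threshold`, giving
#' (`saturation`, `threshold`, `alpha`, `beta`) for PCA, correlation and
#' ANCOVA analyses.
#'
#' Conditions from prepulse-varying and delay-varying experiments are kept
#' apart by the `condition_tag` column when present; analyses in this
#' package never pool across tags.
#'
#' @param fits Cohort fit table from [fit_cohort()].
#' @param type `"full"` (5 features) or `"reduced"` (4 features).
#' @return Tibble with one row per animal x condition; feature columns after
#'   the identifying columns.
#' @export
condition_features <- function(fits, type = c("full", "reduced")) {
  type <- match.arg(type)
  assert_cols(fits, c("animal_id", "fit"), "fit table")
  purrr::map(fits$fit, function(f) {
    sc <- f$scalings
    if (nrow(sc) == 0) return(NULL)
    sc$animal_id <- f$animal_id
    sc$group <- f$group
    if (type == "full") {
      sc$m_max <- f$m_max; sc$r <- f$r; sc$s0 <- f$s0
    } else {
      sc$saturation <- f$m_max
      sc$threshold <- baseline_threshold(f$r, f$s0)
    }
    sc
  }) %>%
    bind_rows() %>%
    select(dplyr::any_of(c("animal_id", "group", "condition_tag",
                           "prepulse_db", "delay_ms")),
           dplyr::everything())
}

feature_cols <- function(features) {
  setdiff(names(features), c("animal_id", "group", "condition_tag",
                             "prepulse_db", "delay_ms"))
}

# z-score each feature column across animals (within a condition); constant
# columns are left centred at 0.
standardize_features <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2, sample_sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sds, "/")
}

feature_matrix <- function(features, standardize = TRUE) {
  X <- as.matrix(features[, feature_cols(features), drop = FALSE])
  if (standardize) X <- standardize_features(X)
  X
}
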