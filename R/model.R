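#' Sigmoid baseline startle curve
#'
#' The startle response above the sound-independent floor is modelled as a
#' logistic function of startle sound level `s` (dB above background):
#' `N(s) = m_max / (1 + exp(-r * (s - s0)))`, where `m_max` is the saturation
#' (asymptotic maximal log-movement), `r` the slope (per dB) and `s0` the
#' midpoint (dB at which the animal startles at half of maximal).
#'
#' @param s Startle sound level(s), dB above background.
#' @param m_max Saturation, log10 z-scored movement units; must be > 0.
#' @param r Slope per dB; must be > 0.
#' @param s0 Midpoint, dB above background.
#' @return Numeric vector of log-movement values in (0, `m_max`).
#' @examples
#' startle_sigmoid(40, m_max = 4, r = 0.2, s0 = 40) # half of saturation
#' @export
startle_sigmoid <- function(s, m_max, r, s0) {
  m_max / (1 + exp(-r * (s - s0)))
}

#' Predicted movement under the scaling model
#'
#' Computes the model mean log-movement for a stimulus: the baseline startle
#' curve scaled along the startle axis by `alpha` and along the sound axis by
#' `beta`, on top of the sound-independent floor `m0`:
#' `m = m0 + alpha * N(beta * s)`. The startle-scaling-only variant fixes
#' `beta = 1`, which is the model that implicitly underlies the traditional
#' PPI ratio. Baseline (no-prepulse) stimuli use `alpha = beta = 1`.
#'
#' @inheritParams startle_sigmoid
#' @param alpha Startle scaling in \[0, 1\] (1 = no scaling).
#' @param beta Sound scaling in \[0, 1\] (1 = no scaling).
#' @param m0 Baseline movement independent of sound (log-movement units).
#' @param variant `"both"` applies `alpha` and `beta`; `"startle_only"`
#'   ignores `beta`.
#' @return Numeric vector of predicted mean log-movement.
#' @export
predicted_movement <- function(s, m_max, r, s0, alpha = 1, beta = 1, m0 = 0,
                               variant = c("both", "startle_only")) {
  variant <- match.arg(variant)
  if (variant == "startle_only") beta <- 1
  m0 + alpha * startle_sigmoid(beta * s, m_max, r, s0)
}

#' Baseline startle threshold
#'
#' The threshold is the sound level at which the baseline curve reaches 5% of
#' its saturation: solving `N(s) = 0.05 * m_max` gives
#' `s = s0 - log(19) / r`. Together with the saturation it summarises the
#' baseline curve in two interpretable numbers (threshold for the sound axis,
#' saturation for the startle axis).
#'
#' @inheritParams startle_sigmoid
#' @return Threshold in dB above background.
#' @export
baseline_threshold <- function(r, s0) {
  if (any(r <= 0)) {
    abort("`r` must be > 0 to invert the sigmoid.", class = "ppiscale_domain_error")
  }
  s0 - log(19) / r
}

#' Convert a scaling parameter to percent scaling
#'
#' Scaling parameters range from 1 (no scaling) to 0 (complete scaling);
#' `100 * (1 - x)` expresses them on the percent scale used by the
#' traditional PPI literature.
#'
#' @param x Scaling value(s) in \[0, 1\].
#' @return Percent scaling in \[0, 100\].
#' @export
percent_scaling <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    abort("Scaling values must lie in [0, 1].", class = "ppiscale_domain_error")
  }
  100 * (1 - x)
}
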