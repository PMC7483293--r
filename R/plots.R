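#' Plot a fitted startle curve with its data
#'
#' Shows the per-stimulus mean log movements (points, with SEM error bars
#' when `summaries` is supplied) and the fitted model curves: the baseline
#' startle curve and one scaled curve per prepulse condition.
#'
#' @param object A `startle_fit`.
#' @param summaries Optional movement summaries to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.startle_fit <- function(object, summaries = NULL, ...) {
  s_grid <- seq(0, 60, length.out = 121)
  curves <- bind_rows(
    tibble(prepulse_db = 0, delay_ms = 0, startle_db = s_grid),
    tidyr::crossing(object$scalings[, c("prepulse_db", "delay_ms")],
                    startle_db = s_grid))
  curves$pred <- predict(object, curves)
  curves$condition <- condition_label(curves$prepulse_db, curves$delay_ms)
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$startle_db, y = .data$pred,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "startle sound (dB above background)",
                  y = "mean log10 movement",
                  colour = "condition",
                  title = sprintf("Startle scaling model: animal %s", object$animal_id)) +
    ggplot2::theme_minimal()
  if (!is.null(summaries)) {
    summaries <- mutate(summaries,
                        condition = condition_label(.data$prepulse_db, .data$delay_ms))
    p <- p +
      ggplot2::geom_point(data = summaries,
                          ggplot2::aes(y = .data$mean_log_movement)) +
      ggplot2::geom_errorbar(data = summaries,
                             ggplot2::aes(y = .data$mean_log_movement,
                                          ymin = .data$mean_log_movement - .data$sem,
                                          ymax = .data$mean_log_movement + .data$sem),
                             width = 1)
  }
  p
}

#' Plot LD projections of two groups
#'
#' @param object A `ppi_lda` from [lda_condition()].
#' @param ... Unused.
#' @return A ggplot object showing each animal's projection onto the linear
#'   discriminant; the dashed line is the separating hyperplane.
#' @exportS3Method ggplot2::autoplot
autoplot.ppi_lda <- function(object, ...) {
  ggplot2::ggplot(object$projections,
                  ggplot2::aes(x = .data$group, y = .data$ld,
                               colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.08, height = 0) +
    ggplot2::geom_hline(yintercept = object$offset, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "LD projection",
                  title = sprintf("Linear discriminant: mean |distance| = %.3f",
                                  object$mean_abs_distance)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot PPI ratio against startle sound level
#'
#' The traditional metric across startle levels, one line per prepulse
#' condition; its systematic decrease with sound level is the diagnostic
#' that motivates the two-axis scaling model.
#'
#' @param ratios Output of [ppi_ratio_table()] (one animal is clearest).
#' @return A ggplot object.
#' @export
plot_ppi_ratio <- function(ratios) {
  ratios <- mutate(ratios,
                   condition = condition_label(.data$prepulse_db, .data$delay_ms))
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$startle_db, y = .data$ppi_ratio,
                                       colour = .data$condition,
                                       group = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", linewidth = 0.5) +
    ggplot2::labs(x = "startle sound (dB above background)", y = "PPI ratio") +
    ggplot2::theme_minimal()
}
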