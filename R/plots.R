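# Plotting conveniences (ggplot2 is an optional dependency); the report's
# numbers, not these figures, are the analysis surface.

#' Scatter plot of a quadratic log-gain vs log-RP fit
#'
#' @param frame Analysis frame from [build_analysis_frame()].
#' @param response_col Gain column to plot (positive values only).
#' @return A ggplot object.
#' @export
plot_gain_vs_rp <- function(frame, response_col = "weight_gain") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- frame[frame$included %in% TRUE & !is.na(frame[[response_col]]) &
               frame[[response_col]] > 0, ]
  d$log_rp <- log10(d$rp_days)
  d$log_y <- log10(d[[response_col]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_rp, y = .data$log_y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sex)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x + I(x^2), se = FALSE,
                         colour = "black") +
    ggplot2::labs(x = "log10 Retzius periodicity (days)",
                  y = paste0("log10 ", response_col)) +
    ggplot2::theme_minimal()
}

#' Velocity curve with staging landmarks for one participant
#'
#' @param model A `growth_curve` from [smooth_series()].
#' @param assessment Optional one-row staging tibble from
#'   [assign_maturity_stage()] to mark the pre-spurt minimum and PHV.
#' @return A ggplot object.
#' @export
plot_velocity <- function(model, assessment = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  p <- ggplot2::ggplot(model$curve, ggplot2::aes(x = .data$age_years, y = .data$velocity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (years)", y = "velocity (cm/yr)",
                  title = paste(model$participant_id, model$variable)) +
    ggplot2::theme_minimal()
  if (!is.null(assessment)) {
    if (!is.na(assessment$phv_age)) {
      p <- p + ggplot2::geom_vline(xintercept = assessment$phv_age, linetype = 2)
    }
    if (!is.na(assessment$prespurt_min_age)) {
      p <- p + ggplot2::geom_vline(xintercept = assessment$prespurt_min_age, linetype = 3)
    }
  }
  p
}
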