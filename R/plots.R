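#' Plot an ERP waveform
#'
#' @param object An `erp_waveform` (from [condition_average()] or
#'   [difference_wave()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.erp_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms,
                                       .data$amplitude_uv)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2,
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time relative to feedback (ms)",
                  y = expression("Amplitude (" * mu * "V)"))
}

#' Learning-curve plot
#'
#' Accuracy per learning block and timing condition, one line per
#' participant with the cohort mean overlaid.
#'
#' @param accuracy An accuracy table from [score_accuracy()].
#' @return A ggplot.
#' @export
plot_learning_curves <- function(accuracy) {
  ggplot2::ggplot(accuracy,
                  ggplot2::aes(.data$block, .data$accuracy,
                               group = .data$participant)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2,
                          colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::facet_wrap(~ timing) +
    ggplot2::labs(x = "Learning block", y = "Proportion correct")
}

#' Latent stimulus-value trajectories of a fit
#'
#' @param fit An `rl_fit`.
#' @param probabilities Optional named reward probabilities to overlay
#'   as dashed reference lines.
#' @return A ggplot.
#' @export
plot_value_trajectories <- function(fit, probabilities = NULL) {
  stopifnot(inherits(fit, "rl_fit"))
  tr <- dplyr::mutate(fit$trajectories, trial = dplyr::row_number())
  long <- tidyr::pivot_longer(tr, dplyr::starts_with("Q"),
                              names_to = "stimulus",
                              values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$trial, .data$value,
                                          colour = .data$stimulus)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trial", y = "Estimated stimulus value Q")
  if (!is.null(probabilities)) {
    ref <- tibble::tibble(stimulus = paste0("Q", seq_along(probabilities)),
                          value = as.numeric(probabilities))
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$value,
                                              colour = .data$stimulus),
                                 linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Simple-slope plot
#'
#' @param slopes Output of [simple_slopes()].
#' @param moderator Moderator column to place on the x axis.
#' @return A ggplot.
#' @export
plot_simple_slopes <- function(slopes, moderator) {
  ggplot2::ggplot(slopes,
                  ggplot2::aes(factor(.data[[moderator]]), .data$slope)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$slope - 1.96 * .data$std.error,
                   ymax = .data$slope + 1.96 * .data$std.error),
      width = 0.15) +
    ggplot2::labs(x = moderator, y = "Conditional slope of the PE")
}
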