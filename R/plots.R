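#' Plot a hypnogram as a state trace over zeitgeber time
#'
#' Step trace of the vigilance state against ZT, with the dark phase
#' shaded. The conventional vertical order places WAKE on top and REM at
#' the bottom.
#'
#' @param hypnogram Hypnogram tibble.
#' @param schedule A [light_dark_schedule()] (for the shading).
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(hypnogram, schedule = light_dark_schedule()) {
  st <- hypnogram_states(hypnogram)
  df <- tibble::tibble(
    hours = hypnogram$epoch * epoch_seconds() / 3600,
    state = factor(as.character(st), levels = rev(vigilance_states()))
  )
  dark_on <- (schedule$lights_off_zt - hypnogram_start_zt(hypnogram)) %% schedule$period
  total_h <- max(df$hours) + epoch_seconds() / 3600
  shade <- tibble::tibble(
    xmin = seq(dark_on, total_h, by = schedule$period),
    xmax = pmin(seq(dark_on, total_h, by = schedule$period) +
                  (schedule$period - schedule$lights_off_zt + schedule$lights_on_zt),
                total_h)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$state, group = 1)) +
    ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "Hours from recording start", y = NULL,
                  title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' Plot a state/phase power spectrum
#'
#' Mean power fraction per 0.5-Hz bin with the classical band boundaries
#' marked.
#'
#' @param profile Tibble from [state_phase_spectrum()] (profiles for
#'   several states/phases may be row-bound).
#' @return A ggplot object.
#' @export
plot_spectral_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$bin_hz, y = .data$power_fraction,
    colour = interaction(.data$state, .data$phase, sep = " / ")
  )) +
    ggplot2::geom_vline(xintercept = band_definitions()$lo_hz,
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power fraction of 0-20 Hz total",
                  colour = NULL, title = "EEG power spectrum") +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot.vigilance_mlp()` shows the training and validation loss per
#' pass; `autoplot.classifier_evaluation()` shows the confusion matrix as a
#' heatmap of counts.
#'
#' @param object A fitted `vigilance_mlp` or a `classifier_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vigilance_mlp <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"pass",
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$pass, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_pass, linetype = "dashed") +
    ggplot2::labs(x = "Pass", y = "Cross-entropy loss", colour = NULL,
                  title = "MLP training history") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vigilance_mlp
#' @export
autoplot.classifier_evaluation <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(object$confusion,
                                              responseName = "n"))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(vigilance_states())) +
    ggplot2::labs(x = "Predicted", y = "True",
                  title = sprintf("Confusion matrix (accuracy %.3f)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
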