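#' Plot MAD profiles
#'
#' Plots per-condition MAD profiles over the phase grid, one panel per
#' signal. Toe-height MADs are shown in millimeters, angle MADs in degrees.
#'
#' @param profiles Tidy profile tibble as from [mad_profile()] or
#'   [run_pipeline()]`$profiles`.
#' @param signal Optional signal name to restrict to.
#' @return A ggplot object.
#' @export
plot_mad_profile <- function(profiles, signal = NULL) {
  if (!is.null(signal)) {
    profiles <- dplyr::filter(profiles, .data$signal == !!signal)
  }
  dat <- profiles |>
    dplyr::mutate(
      mad_display = ifelse(.data$signal == "toe_height",
                           .data$mad * 1000, .data$mad),
      units = ifelse(.data$signal == "toe_height", "mm", "deg")
    ) |>
    dplyr::group_by(.data$condition, .data$signal, .data$phase) |>
    dplyr::summarise(mad = mean(.data$mad_display), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phase, y = .data$mad,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$signal), scales = "free_y") +
    ggplot2::labs(x = "Gait cycle (%)", y = "MAD (mm for toe height, deg for angles)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot normalized cycles
#'
#' Spaghetti plot of per-stride normalized curves for one signal.
#'
#' @param cycles A `gait_cycles` tibble.
#' @param signal Signal to plot (default first present).
#' @return A ggplot object.
#' @export
plot_cycles <- function(cycles, signal = NULL) {
  if (is.null(signal)) signal <- cycles$signal[1]
  dat <- dplyr::filter(cycles, .data$signal == !!signal)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phase, y = .data$value,
                                    group = .data$stride)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "Gait cycle (%)", y = signal) +
    ggplot2::theme_minimal()
}

#' Autoplot method for condition comparisons
#'
#' Shows per-grid-point p-values on a log scale with the Bonferroni
#' threshold, marking significant points.
#'
#' @param object A `gait_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot gait_comparison
#' @export
autoplot.gait_comparison <- function(object, ...) {
  pts <- object$points
  if (!object$gate_passed || all(is.na(pts$p))) {
    warn("Gate not passed; nothing to plot.")
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$phase, y = .data$p,
                                    shape = .data$test,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Gait cycle (%)", y = "one-tailed p",
                  caption = sprintf("dashed: Bonferroni threshold %g",
                                    object$threshold)) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
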