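#' Plot concentration-time profiles per compartment
#'
#' @param series A concentration series (`compound_id`, `compartment`,
#'   `chamber`, `time`, `conc`), e.g. from [concentration_series()].
#' @return A ggplot object: one panel per compound, colour per compartment,
#'   one thin line per chamber.
#' @export
plot_concentration_profiles <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$time, y = .data$conc,
                               colour = .data$compartment,
                               group = interaction(.data$compartment,
                                                   .data$chamber))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$compound_id), scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = "Concentration (µM)",
                  colour = "Compartment") +
    ggplot2::theme_minimal()
}

#' Plot TEER traces with the viability threshold
#'
#' @param teer TEER traces (`chamber`, `time_min`, `resistance`).
#' @param threshold Viability threshold drawn as a dashed line (Ohm cm2).
#' @return A ggplot object.
#' @export
plot_teer <- function(teer, threshold = 15) {
  ggplot2::ggplot(teer, ggplot2::aes(x = .data$time_min,
                                     y = .data$resistance,
                                     group = .data$chamber,
                                     colour = factor(.data$chamber))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Time (min)", y = "TEER (Ω·cm²)",
                  colour = "Chamber") +
    ggplot2::theme_minimal()
}

#' @method autoplot papp_fit
#' @export
autoplot.papp_fit <- function(object, ...) {
  ggplot2::ggplot(object$per_chamber,
                  ggplot2::aes(x = .data$compound_id, y = .data$papp)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$chamber)),
                        position = ggplot2::position_jitter(width = 0.05,
                                                            height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::labs(x = NULL, y = "P_app (cm/s)", colour = "Chamber") +
    ggplot2::theme_minimal()
}

#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$level, y = .data$response)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$replicate))) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::geom_vline(xintercept = c(object$lod, object$loq),
                        linetype = c("dotted", "dashed")) +
    ggplot2::labs(x = "Concentration (nM)", y = "Response",
                  colour = "Replicate",
                  subtitle = sprintf("LOD %.2g nM (dotted), LOQ %.2g nM (dashed)",
                                     object$lod, object$loq)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
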