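# ggplot2 views of the screening results

#' SHAP summary plot
#'
#' Beeswarm-style view of per-participant SHAP attributions, one row per
#' selected variable (ordered by mean absolute attribution), coloured by the
#' feature value rank.
#'
#' @param object An `olst_shap` report from [linear_shap()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.olst_shap <- function(object, ...) {
  ord <- object |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(imp = mean(abs(.data$attribution))) |>
    dplyr::arrange(.data$imp)
  df <- object |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(value_rank = rank(.data$value) / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(variable = factor(.data$variable, levels = ord$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$attribution, y = .data$variable,
                                   colour = .data$value_rank)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 1, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_colour_gradient(low = "#3b4cc0", high = "#b40426",
                                   name = "feature value\n(rank)") +
    ggplot2::labs(x = "SHAP attribution (decision-value units)", y = NULL)
}

#' Probability versus SRS scatter
#'
#' Calibrated High-group probability against the SRS-2 total for each model
#' category, with the sex-specific screening region implied by the truth
#' labels shown through point shape.
#'
#' @param report The result of [probability_srs_report()], or a single
#'   `olst_model`.
#'
#' @return A ggplot object.
#' @export
plot_probability_srs <- function(report) {
  df <- if (inherits(report, "olst_model")) {
    dplyr::mutate(report$predictions, category = report$category)
  } else {
    report$scatter
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$srs_total, y = .data$prob,
                                   colour = .data$truth)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "SRS-2 total score", y = "P(High autistic trait)",
                  colour = "group") +
    ggplot2::ylim(0, 1)
}

#' COP trajectory plot
#'
#' Stabilogram of a trial in the foot-aligned sensor frame.
#'
#' @param object An `olst_cop` trajectory.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.olst_cop <- function(object, ...) {
  df <- tibble(x = object$x[object$valid], y = object$y[object$valid])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mediolateral (cm)", y = "anteroposterior (cm)")
}
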