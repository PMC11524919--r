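# broom-style methods for fitted screening models

#' Tidy a fitted screening model
#'
#' @param x An `olst_model`.
#' @param ... Unused.
#'
#' @return A tibble with one row per selected variable: `term`, `estimate`
#'   (weight on the standardized scale), `center`, `scale`.
#' @export
tidy.olst_model <- function(x, ...) {
  tibble(
    term = names(x$model$weights),
    estimate = unname(x$model$weights),
    center = unname(x$model$center),
    scale = unname(x$model$scale)
  )
}

#' One-row summary of a fitted screening model
#'
#' @param x An `olst_model`.
#' @param ... Unused.
#'
#' @return A one-row tibble: category, mode, selected subset size, cost, and
#'   the LOOCV confusion metrics.
#' @export
glance.olst_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      category = x$category, mode = x$mode, strategy = x$strategy,
      n_selected = length(x$subset), cost = x$cost, n = x$n_rows
    ),
    x$confusion
  )
}

#' Per-participant predictions of a fitted screening model
#'
#' @param x An `olst_model`.
#' @param ... Unused.
#'
#' @return The out-of-fold prediction tibble: id, SRS total, truth,
#'   decision value, predicted label, calibrated High probability.
#' @export
augment.olst_model <- function(x, ...) {
  x$predictions
}
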