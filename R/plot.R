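#' Plot a circuit trajectory
#'
#' Three stacked panels in the style of the package's reference figures:
#' the input with the fast moving average, the fast and slow averages
#' together (the MACD-style band), and the sigmoid-scaled momentum whose
#' sign is the direction prediction.
#'
#' @param object A `circuit_trajectory` from [integrate_circuit()].
#' @param window Optional length-2 time range to zoom into.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_trajectory <- function(object, window = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time >= window[1], .data$time <= window[2])
  }
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(df[c("time", "u", "x")], c("u", "x"),
                        names_to = "series") |>
      dplyr::mutate(panel = "input and fast average"),
    tidyr::pivot_longer(df[c("time", "x", "y")], c("x", "y"),
                        names_to = "series") |>
      dplyr::mutate(panel = "fast and slow averages"),
    tidyr::pivot_longer(df[c("time", "s")], "s", names_to = "series") |>
      dplyr::mutate(panel = "scaled momentum 1000[σ(x - y) - 0.5]")
  ) |>
    dplyr::mutate(panel = factor(.data$panel, levels = unique(.data$panel)))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_hline(
      data = tibble(panel = factor("scaled momentum 1000[σ(x - y) - 0.5]",
                                   levels = levels(long$panel)), y = 0),
      ggplot2::aes(yintercept = .data$y), colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble's deviation distribution
#'
#' Histogram of the per-sequence deviations from the maximum potential
#' accuracy, with the median marked.
#'
#' @param object A `trend_ensemble` from [ensemble_evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$deviation)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$median_deviation,
                        linetype = "dashed") +
    ggplot2::labs(x = "deviation from maximum potential accuracy",
                  y = "sequences",
                  title = sprintf("median deviation %.4g",
                                  object$median_deviation)) +
    ggplot2::theme_minimal()
}

#' Plot an optimization trace
#'
#' Best-so-far objective value against evaluation count, one line per
#' restart.
#'
#' @param object A `trend_opt` from [run_optimization()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_opt <- function(object, ...) {
  df <- object$trace |>
    dplyr::group_by(.data$restart) |>
    dplyr::mutate(best = cummax(ifelse(is.finite(.data$objective),
                                       .data$objective, -Inf))) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$eval, .data$best,
                                   colour = factor(.data$restart))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "objective evaluation", y = "best objective so far",
                  colour = "restart") +
    ggplot2::theme_minimal()
}
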