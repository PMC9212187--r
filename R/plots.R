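# ggplot2 displays for the result containers.

#' Plot an accuracy-versus-subset-size curve
#'
#' Raw per-k accuracies with, optionally, the +/-`halfwidth`-point moving
#' average overlaid.
#'
#' @param object An `accuracy_curve` from [accuracy_vs_k()].
#' @param halfwidth Moving-average half-width; `NULL` suppresses the
#'   smoothed overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_curve <- function(object, halfwidth = 20, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(alpha = 0.45) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::labs(x = "subset cardinality k", y = "accuracy (%)",
                  title = sprintf("%s accuracy vs subset size",
                                  toupper(object$algorithm[1]))) +
    ggplot2::theme_minimal()
  if (!is.null(halfwidth) && nrow(object) > 2) {
    sm <- moving_average(object, halfwidth)
    p <- p + ggplot2::geom_line(data = sm, colour = "firebrick",
                                linewidth = 0.9)
  }
  p
}

#' Plot a feature-presence profile
#'
#' Two panels worth of information in one display: the per-feature
#' selection percentage (`which = "presence"`) or the cumulative number
#' of distinct features used across the runs (`which = "cumulative"`).
#'
#' @param object A `presence_profile` from [feature_presence()].
#' @param which `"presence"` or `"cumulative"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.presence_profile <- function(object,
                                      which = c("presence", "cumulative"),
                                      ...) {
  which <- match.arg(which)
  if (which == "presence") {
    df <- object$counts
    df$pct <- 100 * df$count / object$n_runs
    ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$pct)) +
      ggplot2::geom_col(width = 1) +
      ggplot2::labs(x = "feature index", y = "presence (%)",
                    title = "Feature presence across subsets") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$cumulative,
                    ggplot2::aes(x = .data$run, y = .data$unique_features)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "run", y = "cumulative unique features",
                    title = "Cumulative distinct features") +
      ggplot2::theme_minimal()
  }
}

#' Plot the training history of an MLP fit
#' @param object An `mlp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlp_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "sum of squared errors F(x)",
                  title = "Levenberg-Marquardt training history") +
    ggplot2::theme_minimal()
}
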