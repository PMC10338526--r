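# ggplot2 autoplot methods for the package's result types.

#' Plot a peri-event class average
#'
#' Mean dF/F with a +/-SEM ribbon, event onset marked at time 0.
#'
#' @param object A `perievent_avg` from [class_average()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perievent_avg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Time from event (s)", y = expression(Delta * F / F),
      title = attr(object, "event_class"),
      subtitle = attr(object, "condition_label")
    ) +
    ggplot2::theme_minimal()
}

#' Plot the averaged ROC curve of a decoding result
#'
#' @param object A `decoding_result` from [run_svm_protocol()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  auc <- object$summary$mean[object$summary$metric == "auc"]
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(0, .data$tpr - .data$tpr_sd),
        ymax = pmin(1, .data$tpr + .data$tpr_sd)
      ),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Mean ROC (AUC = %.3f)", auc),
      subtitle = object$event_class
    ) +
    ggplot2::theme_minimal()
}

#' Plot decile-block means with the fitted trend line
#'
#' @param object A `block_summary` from [blockwise_trend()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.block_summary <- function(object, ...) {
  ggplot2::ggplot(object$blocks, ggplot2::aes(x = .data$block, y = .data$mean_metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "steelblue"
    ) +
    ggplot2::scale_x_continuous(breaks = object$blocks$block) +
    ggplot2::labs(
      x = "Session decile block",
      y = sprintf("Mean %s", object$metric),
      title = sprintf(
        "%s: slope %.4g (p = %.3g)",
        object$event_class, object$slope, object$p_value
      ),
      subtitle = object$condition_label
    ) +
    ggplot2::theme_minimal()
}

#' Plot a dF/F trace with an optional event threshold
#'
#' @param object A `dff_trace` from [compute_dff()].
#' @param threshold Optional horizontal threshold line (e.g. 0.02).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dff_trace <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dotted", colour = "red")
  }
  p
}
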