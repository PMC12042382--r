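# Minimal, unstyled plotting helpers for run records.

#' Plot metric trajectories of a distillation experiment
#'
#' One line per run, faceted by metric, across iterations.
#'
#' @param object A `distill_experiment`.
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot distill_experiment
autoplot.distill_experiment <- function(object,
                                        metrics = c("mcc", "ef", "ir"),
                                        ...) {
  long <- tidy(object)
  long <- long[long$metric %in% metrics, ]
  ggplot2::ggplot(long, ggplot2::aes(x = iteration, y = value,
                                     group = run)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
}

#' Plot one distillation run
#'
#' @param object A `distill_run`.
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot distill_run
autoplot.distill_run <- function(object, metrics = c("mcc", "ef", "ir"),
                                 ...) {
  long <- tidy(object)
  long <- long[long$metric %in% metrics, ]
  ggplot2::ggplot(long, ggplot2::aes(x = iteration, y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
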