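#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation into its attempt log
#'
#' @param x An `lt_evaluation`.
#' @param ... Unused.
#' @return The attempt-log tibble (`attempt`, `initiator_id`, `success`,
#'   `final_departed`) with `evaluation_id`, `group_size`, `initial_lt`
#'   prepended.
#' @export
tidy.lt_evaluation <- function(x, ...) {
  dplyr::mutate(
    x$attempts,
    evaluation_id = x$replicate,
    group_size = x$config$group_size,
    initial_lt = x$config$initial_lt,
    .before = 1
  )
}

#' One-row overview of an evaluation
#'
#' @param x An `lt_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble: group size, initial LT, attempts, success
#'   percentage, and the range of final LT values.
#' @export
glance.lt_evaluation <- function(x, ...) {
  tibble::tibble(
    group_size = x$config$group_size,
    initial_lt = x$config$initial_lt,
    n_attempts = nrow(x$attempts),
    success_pct = success_percentage(x),
    final_lt_min = min(x$final_lt),
    final_lt_max = max(x$final_lt),
    seed_used = x$seed_used
  )
}

#' Tidy a segmentation into a segment table
#'
#' @param x An `lt_segmentation`.
#' @param ... Unused.
#' @return A tibble with one row per segment: `segment`, `start`, `end`,
#'   `mean`, `class`.
#' @export
tidy.lt_segmentation <- function(x, ...) {
  tibble::tibble(
    segment = seq_along(x$segment_means),
    start = x$segment_start,
    end = x$segment_end,
    mean = x$segment_means,
    class = x$segment_classes
  )
}

#' Plot the LT trajectories of an evaluation
#'
#' One line per agent: the leadership tendency in effect at each attempt.
#' Differentiated groups show a fan from the common initial value into
#' plateaus at the clip bounds.
#'
#' @param object An `lt_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lt_evaluation <- function(object, ...) {
  hist <- lt_history(object)
  ggplot2::ggplot(
    hist,
    ggplot2::aes(
      x = .data$attempt, y = .data$lt_value,
      group = .data$agent_id, colour = factor(.data$agent_id)
    )
  ) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::labs(
      x = "attempt", y = "leadership tendency",
      title = sprintf(
        "LT history (N = %d, initial LT = %g)",
        object$config$group_size, object$config$initial_lt
      )
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a segmented LT series
#'
#' The observed series with the fitted piecewise-constant segment means
#' overlaid and breakpoints marked.
#'
#' @param object An `lt_segmentation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lt_segmentation <- function(object, ...) {
  obs <- tibble::tibble(index = seq_along(object$series), value = object$series)
  segs <- tidy(object)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(colour = "grey50", linewidth = 0.3) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$mean, yend = .data$mean, colour = .data$class
      ),
      linewidth = 1
    ) +
    ggplot2::geom_vline(
      xintercept = object$breakpoints, linetype = "dashed", colour = "grey30"
    ) +
    ggplot2::labs(x = "index", y = "value", colour = "segment class") +
    ggplot2::theme_minimal()
}

#' Plot treatment-level metric summaries
#'
#' Mean and standard-error bars per group size, one panel per metric,
#' coloured by initial LT — the package's summary view across an
#' experiment grid.
#'
#' @param cells The `cells` tibble from [aggregate_treatments()].
#' @return A ggplot object.
#' @export
plot_treatment_summary <- function(cells) {
  ggplot2::ggplot(
    cells,
    ggplot2::aes(
      x = .data$group_size, y = .data$mean,
      colour = factor(.data$initial_lt), group = factor(.data$initial_lt)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$mean - .data$se,
        ymax = .data$mean + .data$se
      ),
      size = 0.2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(
      x = "group size", y = "mean (+/- SE)", colour = "initial LT"
    ) +
    ggplot2::theme_minimal()
}
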