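#' Success percentage of an evaluation
#'
#' The percentage of movement attempts that ended with the whole group
#' departing, over the entire evaluation (not just after differentiation).
#'
#' @param evaluation An `lt_evaluation`, or any data frame with a logical
#'   `success` column.
#' @return A single percentage in `[0, 100]`.
#' @export
success_percentage <- function(evaluation) {
  att <- if (inherits(evaluation, "lt_evaluation")) {
    evaluation$attempts
  } else {
    evaluation
  }
  stopifnot(is.data.frame(att), "success" %in% names(att))
  100 * mean(att$success)
}

#' Percentage of the group ending an evaluation with a high LT
#'
#' Segments every agent's LT trajectory and reports the percentage of
#' agents whose final segment is classified high (segment mean at or above
#' `high_threshold`) — the share of emerged leaders the group supports at
#' the end of the evaluation.
#'
#' @inheritParams summarize_evaluation
#' @return A single percentage in `[0, 100]`.
#' @export
high_lt_percentage <- function(evaluation,
                               bin_width = NULL,
                               max_breaks = 5,
                               min_segment_fraction = 0.05,
                               high_threshold = 0.775,
                               low_threshold = 0.225) {
  segs <- agent_segmentations(
    evaluation,
    bin_width = bin_width, max_breaks = max_breaks,
    min_segment_fraction = min_segment_fraction,
    high_threshold = high_threshold, low_threshold = low_threshold
  )
  100 * mean(segs$agents$final_class == "high")
}

#' Two-sample t test on per-replicate metrics
#'
#' Pooled-variance (Student) two-sample t test of the difference in means
#' between two sets of per-replicate values, with the Welch variant
#' reported alongside for robustness. When both samples have zero variance
#' the test is degenerate: equal means give `p = 1`, different means give
#' `p = 0` (complete separation).
#'
#' @param sample_a,sample_b Numeric vectors, each of length at least 2.
#' @return A one-row tibble: `t`, `df`, `p_value` (pooled), `t_welch`,
#'   `df_welch`, `p_welch`, `mean_a`, `mean_b`.
#' @examples
#' two_sample_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
two_sample_t_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  ma <- mean(sample_a)
  mb <- mean(sample_b)
  if (va == 0 && vb == 0) {
    sep <- ma != mb
    return(tibble::tibble(
      t = if (sep) sign(ma - mb) * Inf else 0,
      df = length(sample_a) + length(sample_b) - 2,
      p_value = if (sep) 0 else 1,
      t_welch = if (sep) sign(ma - mb) * Inf else 0,
      df_welch = NA_real_,
      p_welch = if (sep) 0 else 1,
      mean_a = ma, mean_b = mb
    ))
  }
  pooled <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  welch <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble::tibble(
    t = unname(pooled$statistic),
    df = unname(pooled$parameter),
    p_value = pooled$p.value,
    t_welch = unname(welch$statistic),
    df_welch = unname(welch$parameter),
    p_welch = welch$p.value,
    mean_a = ma, mean_b = mb
  )
}

#' Aggregate per-evaluation summaries into treatment-level statistics
#'
#' Takes a tibble of per-evaluation summaries (rows from
#' [summarize_evaluation()], optionally with an `adaptive` column) and
#' produces the replicate mean and standard error of each metric per
#' (group size, initial LT, adaptive) treatment cell, together with
#' pairwise Student t tests between cells on each metric (raw p values and
#' Holm-corrected alongside).
#'
#' @param summaries A data frame with one row per evaluation, containing
#'   `group_size`, `initial_lt`, and the metric columns `success_pct`,
#'   `differentiation_fraction`, `high_lt_pct`, `low_to_high`; an
#'   `adaptive` logical column is honoured if present.
#' @return A list with two tibbles: `cells` (`group_size`, `initial_lt`,
#'   `adaptive`, `metric`, `mean`, `se`, `n`) and `comparisons` (pairwise
#'   cell tests per metric: `t`, `df`, `p_raw`, `p_holm`). Metrics reported
#'   as percentages: `success_pct`, `differentiation_pct` (fraction x 100),
#'   `low_to_high_pct` (transitions as % of group size), `high_lt_pct`.
#' @export
aggregate_treatments <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 2)
  df <- summaries |>
    dplyr::mutate(
      adaptive = if ("adaptive" %in% names(summaries)) .data$adaptive else TRUE,
      differentiation_pct = 100 * .data$differentiation_fraction,
      low_to_high_pct = 100 * .data$low_to_high / .data$group_size
    )
  long <- df |>
    dplyr::select(
      "group_size", "initial_lt", "adaptive",
      "success_pct", "differentiation_pct", "low_to_high_pct", "high_lt_pct"
    ) |>
    tidyr::pivot_longer(
      c("success_pct", "differentiation_pct", "low_to_high_pct", "high_lt_pct"),
      names_to = "metric", values_to = "value"
    )
  cells <- long |>
    dplyr::group_by(.data$group_size, .data$initial_lt, .data$adaptive, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )

  keyed <- long |>
    dplyr::mutate(cell = sprintf(
      "N%d_lt%g_%s", .data$group_size, .data$initial_lt,
      ifelse(.data$adaptive, "adaptive", "fixed")
    )) |>
    dplyr::filter(!is.na(.data$value))
  comparisons <- keyed |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(d, key) {
      cells_here <- d |>
        dplyr::group_by(.data$cell) |>
        dplyr::filter(dplyr::n() >= 2) |>
        dplyr::ungroup()
      ids <- sort(unique(cells_here$cell))
      if (length(ids) < 2) {
        return(tibble::tibble())
      }
      pairs <- utils::combn(ids, 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(pr) {
        tt <- two_sample_t_test(
          cells_here$value[cells_here$cell == pr[1]],
          cells_here$value[cells_here$cell == pr[2]]
        )
        tibble::tibble(
          cell_a = pr[1], cell_b = pr[2],
          t = tt$t, df = tt$df, p_raw = tt$p_value
        )
      })
    }) |>
    dplyr::ungroup()
  if (nrow(comparisons) > 0) {
    comparisons <- comparisons |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(p_holm = stats::p.adjust(.data$p_raw, method = "holm")) |>
      dplyr::ungroup()
  }
  list(cells = cells, comparisons = comparisons)
}
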