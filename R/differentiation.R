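#' @importFrom rlang .data %||%
NULL

# Segment every agent's LT trajectory of one evaluation.
#
# Long trajectories are aggregated into fixed-width bins (mean LT per bin,
# targeting ~`target_bins` points) before segmentation; breakpoint indices
# are mapped back to attempt units by multiplying with the bin width. At the
# default width (series length / 400) the attempt-scale resolution is 0.25%
# of an evaluation, far below the precision at which differentiation
# fractions are reported.
agent_segmentations <- function(evaluation,
                                bin_width = NULL,
                                target_bins = 400L,
                                max_breaks = 5,
                                min_segment_fraction = 0.05,
                                high_threshold = 0.775,
                                low_threshold = 0.225) {
  stopifnot(inherits(evaluation, "lt_evaluation"))
  n_attempts <- nrow(evaluation$attempts)
  bw <- as.integer(bin_width %||% max(1, round(n_attempts / target_bins)))
  bin_id <- ceiling(seq_len(n_attempts) / bw)
  res <- purrr::map(seq_len(evaluation$config$group_size), function(id) {
    y <- dense_lt_series(evaluation, id)
    binned <- as.numeric(rowsum(y, bin_id) / tabulate(bin_id))
    seg <- segment_series(
      binned,
      max_breaks = max_breaks,
      min_segment_fraction = min_segment_fraction,
      high_threshold = high_threshold,
      low_threshold = low_threshold
    )
    fh_bins <- first_high_emergence(seg)
    tibble::tibble(
      agent_id = id,
      first_high_attempt = if (is.na(fh_bins)) NA_integer_ else as.integer(fh_bins * bw),
      final_class = seg$segment_classes[length(seg$segment_classes)],
      final_lt = evaluation$final_lt[id],
      n_segments = length(seg$segment_means),
      segmentation = list(seg)
    )
  })
  list(bin_width = bw, agents = dplyr::bind_rows(res))
}

#' Differentiation summary of one evaluation
#'
#' Reconstructs every agent's dense LT trajectory, segments it
#' ([segment_series()]), and summarizes when and how the group
#' differentiated into leaders and followers: the earliest attempt at which
#' any agent's LT emerged as high (segment mean at or above
#' `high_threshold`), that attempt as a fraction of the evaluation length,
#' the number of post-differentiation low-to-high and high-to-low class
#' transitions summed over agents, and the number of agents whose final
#' segment is high.
#'
#' @param evaluation An `lt_evaluation` from [run_evaluation()].
#' @param bin_width Attempts per aggregation bin before segmentation;
#'   `NULL` (default) targets ~400 bins.
#' @param max_breaks,min_segment_fraction,high_threshold,low_threshold
#'   Passed to [segment_series()].
#' @return A one-row tibble: `evaluation_id`, `group_size`, `initial_lt`,
#'   `n_attempts`, `success_pct`, `differentiation_attempt` (`NA` if no
#'   agent ever emerged high), `differentiation_fraction`, `low_to_high`,
#'   `high_to_low`, `final_high_count`, `high_lt_pct`, plus a list-column
#'   `agents` with the per-agent table (first high attempt, final class,
#'   final LT, segmentation object).
#' @examples
#' cfg <- evaluation_config(group_size = 10, attempts_multiplier = 100)
#' ev <- run_evaluation(cfg, replicate = 1)
#' summarize_evaluation(ev, bin_width = 2)
#' @export
summarize_evaluation <- function(evaluation,
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
  ag <- segs$agents
  n_attempts <- nrow(evaluation$attempts)
  diff_attempt <- if (all(is.na(ag$first_high_attempt))) {
    NA_integer_
  } else {
    min(ag$first_high_attempt, na.rm = TRUE)
  }
  trans <- purrr::map(
    ag$segmentation, count_transitions,
    differentiation_index = if (is.na(diff_attempt)) 0 else diff_attempt / segs$bin_width
  )
  tibble::tibble(
    evaluation_id = evaluation$replicate,
    group_size = evaluation$config$group_size,
    initial_lt = evaluation$config$initial_lt,
    n_attempts = n_attempts,
    success_pct = success_percentage(evaluation),
    differentiation_attempt = diff_attempt,
    differentiation_fraction = diff_attempt / n_attempts,
    low_to_high = sum(purrr::map_int(trans, "low_to_high")),
    high_to_low = sum(purrr::map_int(trans, "high_to_low")),
    final_high_count = sum(ag$final_class == "high"),
    high_lt_pct = 100 * mean(ag$final_class == "high"),
    agents = list(ag |> dplyr::select(-"segmentation"))
  )
}
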