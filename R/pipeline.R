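#' Default full configuration
#'
#' The complete study-scale configuration: Table-of-observed-constants rate
#' parameters, learning rate 0.02 with LT bounds `[0.1, 0.9]`, treatment
#' grid of group sizes 10–150 crossed with initial LTs
#' `{0.2, 0.5, 0.8}`, 2000 x N attempts per evaluation, 50 replicates.
#' Desk-scale runs override the grid and counts.
#'
#' @param ... Overrides as `key = value`; nested groups `model` and
#'   `adapt` take named lists.
#' @return A list of class `leadsim_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    model = unclass(model_params()),
    adapt = unclass(adapt_params()),
    group_sizes = c(10, 15, seq(20, 150, by = 10)),
    initial_lts = c(0.2, 0.5, 0.8),
    attempts_multiplier = 2000,
    replicate_count = 50,
    seed = 1L
  )
  apply_config_overrides(cfg, list(...))
}

apply_config_overrides <- function(cfg, overrides) {
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) {
      stop("unknown configuration key: `", key, "`.", call. = FALSE)
    }
    if (key %in% c("model", "adapt")) {
      sub <- overrides[[key]]
      if (!is.list(sub)) stop("`", key, "` must be a named list.", call. = FALSE)
      bad <- setdiff(names(sub), names(cfg[[key]]))
      if (length(bad) > 0) {
        stop("unknown `", key, "` key(s): ", paste0("`", bad, "`", collapse = ", "),
          ".",
          call. = FALSE
        )
      }
      cfg[[key]][names(sub)] <- sub
    } else {
      cfg[[key]] <- overrides[[key]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  model <- do.call(model_params, cfg$model) # range-checks every constant
  adapt <- do.call(adapt_params, cfg$adapt)
  if (any(cfg$group_sizes < 2)) {
    stop("`group_sizes` must all be at least 2.", call. = FALSE)
  }
  if (any(cfg$initial_lts < adapt$lt_min | cfg$initial_lts > adapt$lt_max)) {
    stop("`initial_lts` must lie within [lt_min, lt_max].", call. = FALSE)
  }
  if (cfg$attempts_multiplier < 1) {
    stop("`attempts_multiplier` must be at least 1.", call. = FALSE)
  }
  if (cfg$replicate_count < 1) {
    stop("`replicate_count` must be at least 1.", call. = FALSE)
  }
  cfg$model <- unclass(model)
  cfg$adapt <- unclass(adapt)
  cfg$group_sizes <- as.integer(cfg$group_sizes)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "leadsim_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML file of configuration overrides and applies them on top of
#' [default_config()]. An empty file yields the full default
#' configuration; unknown or out-of-range keys raise an error naming the
#' offending key.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `leadsim_config`.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines("group_sizes: [10, 20]\nreplicate_count: 3", f)
#' cfg <- load_config(f)
#' cfg$group_sizes
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  do.call(default_config, overrides)
}

#' Run the full simulate-analyze-report pipeline
#'
#' Runs the treatment grid of a configuration, summarizes every evaluation
#' with the changepoint analysis, aggregates treatment-level statistics,
#' and writes all artifacts under `out_dir`:
#' * `attempts_<cell>.csv` — attempt logs (`evaluation_id`, `attempt`,
#'   `initiator_id`, `success` 0/1, `final_departed`);
#' * `lt_history_<cell>.csv` — sparse LT change records (`evaluation_id`,
#'   `agent_id`, `attempt`, `lt_value`);
#' * `config_<cell>.json` — sidecar echoing the cell config and seeds;
#' * `summaries.csv` — one row per evaluation (differentiation metrics);
#' * `treatment_summary.csv`, `comparisons.csv` — aggregated statistics;
#' * `manifest.json` — full config echo, base seed, file inventory.
#'
#' Rerunning with the same configuration reproduces every output
#' byte-for-byte.
#'
#' @param config A `leadsim_config` (see [default_config()],
#'   [load_config()]).
#' @param out_dir Output directory, created if missing.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "leadsim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- do.call(model_params, config$model)
  adapt <- do.call(adapt_params, config$adapt)
  grid <- run_treatment_grid(
    group_sizes = config$group_sizes,
    initial_lts = config$initial_lts,
    attempts_multiplier = config$attempts_multiplier,
    replicate_count = config$replicate_count,
    seed = config$seed,
    model = model, adapt = adapt, quiet = quiet
  )

  files <- character(0)
  cells <- dplyr::distinct(grid, .data$group_size, .data$initial_lt)
  for (i in seq_len(nrow(cells))) {
    n <- cells$group_size[i]
    l0 <- cells$initial_lt[i]
    tag <- sprintf("N%d_lt%g", n, l0)
    rows <- grid[grid$group_size == n & grid$initial_lt == l0, ]
    att <- purrr::map_dfr(rows$evaluation, function(ev) {
      dplyr::mutate(ev$attempts,
        evaluation_id = ev$replicate,
        success = as.integer(.data$success), .before = 1
      )
    })
    hist <- purrr::map_dfr(rows$evaluation, function(ev) {
      dplyr::mutate(ev$lt_changes, evaluation_id = ev$replicate, .before = 1)
    })
    f_att <- file.path(out_dir, paste0("attempts_", tag, ".csv"))
    f_hist <- file.path(out_dir, paste0("lt_history_", tag, ".csv"))
    f_cfg <- file.path(out_dir, paste0("config_", tag, ".json"))
    readr::write_csv(att[, c(
      "evaluation_id", "attempt", "initiator_id", "success", "final_departed"
    )], f_att)
    readr::write_csv(hist[, c("evaluation_id", "agent_id", "attempt", "lt_value")], f_hist)
    jsonlite::write_json(
      list(
        group_size = n, initial_lt = l0,
        attempts_multiplier = config$attempts_multiplier,
        replicate_count = config$replicate_count,
        base_seed = config$seed,
        seeds = rows$seed_used,
        model = config$model, adapt = config$adapt
      ),
      f_cfg,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    files <- c(files, f_att, f_hist, f_cfg)
  }

  if (!quiet) message("segmenting LT histories")
  summaries <- purrr::map_dfr(grid$evaluation, summarize_evaluation) |>
    dplyr::select(-"agents") |>
    dplyr::mutate(adaptive = adapt$adaptive)
  f_sum <- file.path(out_dir, "summaries.csv")
  readr::write_csv(summaries, f_sum)

  agg <- aggregate_treatments(summaries)
  f_cells <- file.path(out_dir, "treatment_summary.csv")
  f_comp <- file.path(out_dir, "comparisons.csv")
  readr::write_csv(agg$cells, f_cells)
  readr::write_csv(agg$comparisons, f_comp)

  manifest <- list(
    package_version = as.character(utils::packageVersion("leadsim")),
    config = unclass(config),
    base_seed = config$seed,
    files = basename(c(files, f_sum, f_cells, f_comp))
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Rebuild an evaluation object from on-disk logs
#'
#' Reconstructs an `lt_evaluation` from the attempt-log and LT-history
#' tables written by [run_pipeline()], so the changepoint analysis and
#' reporting stages can be rerun without re-simulating.
#'
#' @param attempts A data frame with columns `evaluation_id`, `attempt`,
#'   `initiator_id`, `success`, `final_departed` (one evaluation's rows).
#' @param lt_changes A data frame with columns `agent_id`, `attempt`,
#'   `lt_value` for the same evaluation.
#' @param group_size,initial_lt Treatment-cell identifiers.
#' @param replicate Evaluation id (default from `attempts$evaluation_id`).
#' @return An `lt_evaluation`.
#' @export
evaluation_from_logs <- function(attempts, lt_changes, group_size, initial_lt,
                                 replicate = NULL) {
  replicate <- replicate %||% attempts$evaluation_id[1] %||% 1L
  att <- tibble::tibble(
    attempt = as.integer(attempts$attempt),
    initiator_id = as.integer(attempts$initiator_id),
    success = as.logical(attempts$success),
    final_departed = as.integer(attempts$final_departed)
  )
  chg <- tibble::tibble(
    agent_id = as.integer(lt_changes$agent_id),
    attempt = as.integer(lt_changes$attempt),
    lt_value = as.numeric(lt_changes$lt_value)
  )
  final_lt <- chg |>
    dplyr::group_by(.data$agent_id) |>
    dplyr::slice_max(.data$attempt, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$agent_id) |>
    dplyr::pull(.data$lt_value)
  cfg <- evaluation_config(
    group_size = group_size, initial_lt = initial_lt,
    attempts_multiplier = max(1L, nrow(att) %/% group_size)
  )
  structure(
    list(
      attempts = att, lt_changes = chg, final_lt = final_lt,
      config = cfg, replicate = as.integer(replicate), seed_used = NA_integer_
    ),
    class = "lt_evaluation"
  )
}
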