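#' Configuration for one evaluation treatment cell
#'
#' An evaluation is a long sequence of movement attempts in which LT values
#' persist from one attempt to the next (and are reset only between
#' evaluations). A treatment cell is defined by the group size and the
#' common initial LT; the number of attempts scales with group size so
#' every cell offers comparable per-capita experience.
#'
#' @param group_size Number of agents `N` (`>= 2`).
#' @param initial_lt Starting LT shared by all agents (conventionally 0.2
#'   low, 0.5 moderate, 0.8 high).
#' @param attempts_multiplier Attempts per evaluation = `multiplier * N`
#'   (default 2000, the full study scale; reduce for desk-scale runs).
#' @param replicate_count Number of replicate evaluations (default 50).
#' @param seed Base RNG seed; per-replicate seeds are derived with
#'   [derive_seed()] from `(seed, replicate)` only, never from the
#'   treatment, so replicate `r` is matched across cells.
#' @param model A [model_params()] object.
#' @param adapt An [adapt_params()] object.
#' @return An object of class `lt_eval_config`.
#' @export
evaluation_config <- function(group_size = 10,
                              initial_lt = 0.5,
                              attempts_multiplier = 2000,
                              replicate_count = 50,
                              seed = 1L,
                              model = model_params(),
                              adapt = adapt_params()) {
  model <- as_model_params(model)
  adapt <- as_adapt_params(adapt)
  stopifnot(group_size >= 2, attempts_multiplier >= 1, replicate_count >= 1)
  if (initial_lt < adapt$lt_min || initial_lt > adapt$lt_max) {
    stop("`initial_lt` must lie within [lt_min, lt_max].", call. = FALSE)
  }
  structure(
    list(
      group_size = as.integer(group_size),
      initial_lt = initial_lt,
      attempts_multiplier = as.integer(attempts_multiplier),
      replicate_count = as.integer(replicate_count),
      seed = as.integer(seed),
      model = model,
      adapt = adapt
    ),
    class = "lt_eval_config"
  )
}

#' Derive the RNG seed for one replicate evaluation
#'
#' A deterministic function of the base seed and the replicate index only.
#' Treatment parameters never enter the derivation, so replicate `r` of
#' every treatment cell starts from the same random state — matched seeding
#' across treatments.
#'
#' @param base_seed Base seed (integer).
#' @param replicate Replicate index (1-based integer).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, replicate) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (as.numeric(base_seed) %% m) * 48271 + as.numeric(replicate) * 1000003
  as.integer(s %% m + 1)
}

#' Run one replicate evaluation
#'
#' Runs `attempts_multiplier * group_size` sequential movement attempts
#' with all agents starting at `initial_lt`, LT values carried over between
#' attempts, and (in adaptive mode) the initiator reinforced after every
#' attempt.
#'
#' @param config An [evaluation_config()].
#' @param replicate Replicate index (1-based); seeds the run via
#'   [derive_seed()].
#' @return An object of class `lt_evaluation`: a list with
#'   * `attempts`: tibble of `attempt`, `initiator_id`, `success`,
#'     `final_departed` (one row per attempt);
#'   * `lt_changes`: tibble of `agent_id`, `attempt`, `lt_value` change
#'     records (attempt 0 rows carry the initial value; a record at attempt
#'     `t` takes effect from attempt `t + 1`);
#'   * `final_lt`: numeric vector of LT values after the last attempt;
#'   * `config`, `replicate`, `seed_used`.
#' @examples
#' cfg <- evaluation_config(group_size = 10, attempts_multiplier = 20)
#' ev <- run_evaluation(cfg, replicate = 1)
#' dplyr::count(ev$attempts, success)
#' @export
run_evaluation <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "lt_eval_config"))
  seed_used <- derive_seed(config$seed, replicate)
  n <- config$group_size
  n_attempts <- config$attempts_multiplier * n
  set.seed(seed_used)
  raw <- run_attempts_cpp(
    n, n_attempts, rep(config$initial_lt, n),
    unclass(config$model), unclass(config$adapt),
    record_events = FALSE
  )
  attempts <- tibble::tibble(
    attempt = seq_len(n_attempts),
    initiator_id = raw$initiator_id,
    success = raw$success,
    final_departed = raw$final_departed
  )
  lt_changes <- dplyr::bind_rows(
    tibble::tibble(
      agent_id = seq_len(n), attempt = 0L, lt_value = config$initial_lt
    ),
    tibble::tibble(
      agent_id = raw$change_agent,
      attempt = raw$change_attempt,
      lt_value = raw$change_value
    )
  )
  structure(
    list(
      attempts = attempts,
      lt_changes = lt_changes,
      final_lt = raw$final_lt,
      config = config,
      replicate = as.integer(replicate),
      seed_used = seed_used
    ),
    class = "lt_evaluation"
  )
}

#' @export
print.lt_evaluation <- function(x, ...) {
  cat(sprintf(
    "<lt_evaluation> N = %d, initial LT = %g, %d attempts, %.1f%% success (replicate %d, seed %d)\n",
    x$config$group_size, x$config$initial_lt, nrow(x$attempts),
    100 * mean(x$attempts$success), x$replicate, x$seed_used
  ))
  invisible(x)
}

#' Dense LT history of an evaluation
#'
#' Reconstructs, from the sparse change records, each agent's LT value in
#' effect during every attempt (piecewise-constant carry-forward: an
#' agent's LT changes only at attempts it initiated, taking effect from the
#' following attempt).
#'
#' @param evaluation An `lt_evaluation`.
#' @param agents Agent ids to densify (default all).
#' @return A tibble of `agent_id`, `attempt`, `lt_value`, one row per agent
#'   per attempt.
#' @export
lt_history <- function(evaluation, agents = NULL) {
  stopifnot(inherits(evaluation, "lt_evaluation"))
  n_attempts <- nrow(evaluation$attempts)
  ids <- agents %||% seq_len(evaluation$config$group_size)
  purrr::map_dfr(ids, function(id) {
    tibble::tibble(
      agent_id = id,
      attempt = seq_len(n_attempts),
      lt_value = dense_lt_series(evaluation, id)
    )
  })
}

# Dense series for one agent: value in effect during attempts 1..T.
dense_lt_series <- function(evaluation, agent_id) {
  n_attempts <- nrow(evaluation$attempts)
  chg <- evaluation$lt_changes[evaluation$lt_changes$agent_id == agent_id, ]
  chg <- chg[order(chg$attempt), ]
  # change at attempt t is in effect from attempt t + 1
  idx <- findInterval(seq_len(n_attempts) - 1L, chg$attempt)
  chg$lt_value[idx]
}

#' Run a grid of treatments with matched seeding
#'
#' Runs every (group size, initial LT) treatment cell for the requested
#' number of replicates. Replicate `r` of every cell uses the seed derived
#' from `(seed, r)`, so treatments are compared under matched initial
#' random states.
#'
#' @param group_sizes Integer vector of group sizes.
#' @param initial_lts Numeric vector of initial LT values.
#' @param attempts_multiplier,replicate_count,seed,model,adapt Passed to
#'   [evaluation_config()] for every cell.
#' @param quiet Suppress per-cell progress messages.
#' @return A tibble with one row per evaluation: `group_size`,
#'   `initial_lt`, `replicate`, `seed_used`, `adaptive`, and a list-column
#'   `evaluation` of `lt_evaluation` objects.
#' @export
run_treatment_grid <- function(group_sizes,
                               initial_lts,
                               attempts_multiplier = 2000,
                               replicate_count = 50,
                               seed = 1L,
                               model = model_params(),
                               adapt = adapt_params(),
                               quiet = FALSE) {
  stopifnot(length(group_sizes) >= 1, length(initial_lts) >= 1)
  cells <- tidyr::expand_grid(
    group_size = as.integer(group_sizes),
    initial_lt = initial_lts,
    replicate = seq_len(replicate_count)
  )
  cells |>
    dplyr::mutate(
      evaluation = purrr::pmap(
        list(.data$group_size, .data$initial_lt, .data$replicate),
        function(n, l0, rep_i) {
          if (!quiet) {
            message(sprintf(
              "evaluation: N = %d, initial LT = %g, replicate %d", n, l0, rep_i
            ))
          }
          cfg <- evaluation_config(
            group_size = n, initial_lt = l0,
            attempts_multiplier = attempts_multiplier,
            replicate_count = replicate_count,
            seed = seed, model = model, adapt = adapt
          )
          run_evaluation(cfg, replicate = rep_i)
        }
      ),
      seed_used = purrr::map_int(.data$evaluation, "seed_used"),
      adaptive = adapt$adaptive
    )
}
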