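#' Draw an exponential event waiting time
#'
#' All events in the model are generated by exponential clocks: the waiting
#' time to an event occurring at a given rate is drawn from an exponential
#' distribution with that rate. Deterministic given the RNG state.
#'
#' @param rate Event rate in events per time unit; must be strictly
#'   positive. A rate of exactly zero means the event cannot happen and the
#'   clock must not be drawn at all.
#' @param n Number of independent draws.
#' @return Waiting time(s) with mean `1 / rate`.
#' @export
draw_event_time <- function(rate, n = 1L) {
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("`rate` must be strictly positive; impossible events (rate 0) must ",
      "not draw a clock.",
      call. = FALSE
    )
  }
  stats::rexp(n, rate = rate)
}

#' Initiation competition
#'
#' Every agent draws an initiation time at its own rate `k(L_i) / tau_o`;
#' the earliest clock wins and that agent departs as the initiator. Once an
#' initiation has occurred no other agent may initiate, so the remaining
#' clocks are discarded. With identical LTs the initiator is uniform over
#' agents; in general agent `i` wins with probability proportional to
#' `k(L_i)`.
#'
#' @param lt Numeric vector of current LT values, one per agent (length
#'   `>= 2`).
#' @param params A [model_params()] object.
#' @return A list with `initiator_id` (1-based agent index) and `time` (the
#'   winning initiation time).
#' @export
select_initiator <- function(lt, params = model_params()) {
  if (length(lt) < 2L) stop("need a group of at least 2 agents.", call. = FALSE)
  times <- draw_event_time(initiation_rate(lt, params), n = length(lt))
  # which.min breaks exact ties towards the lowest agent index
  id <- which.min(times)
  list(initiator_id = id, time = times[[id]])
}

#' Simulate one collective movement attempt
#'
#' Runs a single initiation-to-termination episode of the event-driven
#' model. After the initiation competition ([select_initiator()]), the
#' engine repeatedly draws one follow clock per non-departed agent (rate
#' `1 / tau_r`, each with its own k factor and the current departed count
#' `r`) and one cancel clock for the initiator (rate `C_r`), applies the
#' earliest event, and redraws all clocks with the updated `r` —
#' memorylessness of the exponential makes redrawing equivalent to advancing
#' the pending clocks. The attempt ends in success when all `n` agents have
#' departed, or in failure the moment the cancel clock fires first. In
#' adaptive mode the initiator's LT (and only the initiator's) is then
#' reinforced with [update_lt()].
#'
#' This is the readable reference implementation used for single attempts
#' and event-log inspection; [run_evaluation()] uses a compiled engine with
#' the same event law for long attempt sequences.
#'
#' @param lt Numeric vector of current LT values, one per agent.
#' @param params A [model_params()] object.
#' @param adapt An [adapt_params()] object.
#' @return A list of class `lt_attempt` with elements `initiator_id`,
#'   `success`, `final_departed`, `event_log` (a tibble of `event`,
#'   `agent_id`, `time` with strictly increasing times), `initiator_lt_before`,
#'   `initiator_lt_after`, and `lt` (the post-attempt LT vector).
#' @examples
#' set.seed(1)
#' att <- simulate_attempt(rep(0.5, 10))
#' att$event_log
#' @export
simulate_attempt <- function(lt, params = model_params(),
                             adapt = adapt_params()) {
  params <- as_model_params(params)
  adapt <- as_adapt_params(adapt)
  n <- length(lt)
  if (n < 2L) stop("need a group of at least 2 agents.", call. = FALSE)

  ini <- select_initiator(lt, params)
  init_id <- ini$initiator_id
  now <- ini$time
  departed <- rep(FALSE, n)
  departed[init_id] <- TRUE
  ev_kind <- "initiate"
  ev_agent <- init_id
  ev_time <- now
  ok <- TRUE

  while (sum(departed) < n) {
    r <- sum(departed)
    cand <- which(!departed)
    tau <- following_time_constant(lt[cand], n = n, r = r, params = params)
    t_follow <- draw_event_time(1 / tau, n = length(cand))
    t_cancel <- draw_event_time(cancel_rate(lt[init_id], r = r, params = params))
    if (t_cancel < min(t_follow)) {
      now <- now + t_cancel
      ev_kind <- c(ev_kind, "cancel")
      ev_agent <- c(ev_agent, init_id)
      ev_time <- c(ev_time, now)
      ok <- FALSE
      break
    }
    who <- cand[which.min(t_follow)]
    now <- now + min(t_follow)
    departed[who] <- TRUE
    ev_kind <- c(ev_kind, "follow")
    ev_agent <- c(ev_agent, who)
    ev_time <- c(ev_time, now)
  }

  lt_before <- lt[init_id]
  if (adapt$adaptive) {
    lt[init_id] <- update_lt(lt[init_id], ok, adapt)
  }
  structure(
    list(
      initiator_id = init_id,
      success = ok,
      final_departed = sum(departed),
      event_log = tibble::tibble(
        event = ev_kind, agent_id = ev_agent, time = ev_time
      ),
      initiator_lt_before = lt_before,
      initiator_lt_after = lt[init_id],
      lt = lt
    ),
    class = "lt_attempt"
  )
}

#' @export
print.lt_attempt <- function(x, ...) {
  cat(sprintf(
    "<lt_attempt> initiator %d, %s, %d departed, %d events\n",
    x$initiator_id, if (x$success) "success" else "cancelled",
    x$final_departed, nrow(x$event_log)
  ))
  invisible(x)
}
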