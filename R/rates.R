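#' The LT-to-rate-modifier sigmoid ("k factor")
#'
#' Converts an effective leadership tendency into the multiplicative rate
#' modifier `k = k_max / (1 + exp((center - l_prime) * slope))`. With the
#' default shape (center 0.5, slope 10, `k_max` 2), `k(0.5) = 1` leaves the
#' baseline model untouched, and `k(l) + k(1 - l) = 2` for every `l`, so low
#' and high tendencies perturb the rates with equal magnitude in opposite
#' directions.
#'
#' @param l_prime Effective LT value(s), strictly inside (0, 1). For
#'   initiation decisions this is the LT itself; for following and
#'   cancellation it is `1 - lt` (see [effective_l_prime()]).
#' @param params A [model_params()] object.
#' @return Numeric vector of k factors in `(0, k_max)`.
#' @examples
#' k_factor(c(0.1, 0.5, 0.9), model_params())
#' @export
k_factor <- function(l_prime, params = model_params()) {
  params <- as_model_params(params)
  if (any(!is.finite(l_prime)) || any(l_prime <= 0) || any(l_prime >= 1)) {
    stop("`l_prime` must lie strictly inside (0, 1); LT clipping upstream ",
      "should guarantee this.",
      call. = FALSE
    )
  }
  params$k_max / (1 + exp((params$sigmoid_center - l_prime) * params$sigmoid_slope))
}

#' Effective LT for a decision kind
#'
#' The sigmoid argument is the LT itself for initiation decisions and its
#' complement `1 - lt` for following and cancellation decisions: a high-LT
#' individual initiates more and follows/cancels less.
#'
#' @param lt LT value(s) in the clipped range.
#' @param decision_kind One of `"initiate"`, `"follow"`, `"cancel"`.
#' @return `lt` for initiation, `1 - lt` otherwise.
#' @export
effective_l_prime <- function(lt, decision_kind = c("initiate", "follow", "cancel")) {
  decision_kind <- match.arg(decision_kind)
  if (decision_kind == "initiate") lt else 1 - lt
}

#' Initiation rate of one individual
#'
#' Every individual initiates movement attempts at rate `k(lt) / tau_o`;
#' with all individuals at LT 0.5 this reduces to the baseline `1 / tau_o`.
#'
#' @inheritParams k_factor
#' @param lt LT value(s) of the individual(s).
#' @return Initiation rate(s) in events per time unit; increasing in `lt`.
#' @examples
#' initiation_rate(0.5) # 1/1290
#' @export
initiation_rate <- function(lt, params = model_params()) {
  params <- as_model_params(params)
  k_factor(effective_l_prime(lt, "initiate"), params) / params$tau_o
}

#' Following time constant for a candidate follower
#'
#' The per-candidate time constant
#' `tau_r = (1/k) * (alpha_f + beta_f * (n - r) / r)` with
#' `k = k(1 - lt)`; the candidate follows at rate `1 / tau_r`. The departed
#' count `r` includes the initiator, so `r >= 1` whenever following is
#' possible and the mimetic amplification (faster joining as the moving
#' group grows) enters through `(n - r) / r`.
#'
#' @inheritParams k_factor
#' @param lt LT of the candidate follower.
#' @param n Group size (`n >= 2`).
#' @param r Number of departed individuals including the initiator
#'   (`1 <= r <= n - 1`).
#' @return Time constant(s) in time units; high-LT candidates are slower
#'   followers.
#' @examples
#' following_time_constant(0.5, n = 10, r = 1) # 840.9
#' @export
following_time_constant <- function(lt, n, r, params = model_params()) {
  params <- as_model_params(params)
  if (any(n < 2)) stop("`n` must be at least 2.", call. = FALSE)
  if (any(r < 1) || any(r > n - 1)) {
    stop("`r` must satisfy 1 <= r <= n - 1 (departed count includes the ",
      "initiator).",
      call. = FALSE
    )
  }
  k <- k_factor(effective_l_prime(lt, "follow"), params)
  (params$alpha_f + params$beta_f * (n - r) / r) / k
}

#' Cancellation rate of the initiator
#'
#' `C_r = k * alpha_c / (1 + (r / gamma_c)^epsilon_c)` with
#' `k = k(1 - lt)`: the more individuals have departed, the less likely the
#' initiator is to abort, and high-LT initiators cancel less at every stage.
#' The rate stays strictly positive for every `r`, so an attempt can fail
#' even with all but one member departed.
#'
#' @inheritParams k_factor
#' @param lt LT of the initiator.
#' @param r Number of departed individuals including the initiator (`r >= 1`).
#' @return Cancellation rate(s) in events per time unit; decreasing in both
#'   `lt` and `r`.
#' @examples
#' cancel_rate(0.5, r = 2) # 0.0045
#' @export
cancel_rate <- function(lt, r, params = model_params()) {
  params <- as_model_params(params)
  if (any(r < 1)) stop("`r` must be at least 1.", call. = FALSE)
  k <- k_factor(effective_l_prime(lt, "cancel"), params)
  k * params$alpha_c / (1 + (r / params$gamma_c)^params$epsilon_c)
}

#' Reinforcement update of a leadership tendency
#'
#' Applies the bounded linear learning rule
#' `L' = clip(L * (1 - lambda) + lambda * reward, lt_min, lt_max)` with
#' `reward = reward_success` after success and `reward_failure` after
#' failure. Only the initiator of an attempt is updated; repeated success
#' drives LT to `lt_max` and repeated failure to `lt_min`.
#'
#' @param lt Current LT value(s).
#' @param success Logical: did the attempt end with the whole group moving?
#' @param adapt An [adapt_params()] object.
#' @return Updated LT value(s), truncated to `[lt_min, lt_max]`.
#' @examples
#' update_lt(0.5, TRUE, adapt_params()) # 0.51
#' update_lt(0.1, FALSE, adapt_params()) # stays at the lower bound
#' @export
update_lt <- function(lt, success, adapt = adapt_params()) {
  adapt <- as_adapt_params(adapt)
  reward <- ifelse(success, adapt$reward_success, adapt$reward_failure)
  out <- lt * (1 - adapt$lambda_rate) + adapt$lambda_rate * reward
  pmin(pmax(out, adapt$lt_min), adapt$lt_max)
}
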