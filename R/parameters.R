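#' Rate-model parameters for the collective-movement model
#'
#' Constructs the parameter set of the mimetic collective-movement model:
#' the observed rate constants for initiation, following, and cancellation,
#' plus the shape constants of the sigmoid that converts a leadership
#' tendency (LT) into a multiplicative rate modifier (the "k factor").
#'
#' The defaults are the constants estimated from direct observation of
#' collective movement attempts in a group of ten white-faced capuchin
#' monkeys, later confirmed in sheep groups. All individuals initiate at
#' base rate `1/tau_o`; followers join at rate `1/tau_r` with
#' `tau_r = alpha_f + beta_f * (N - r) / r`; the initiator cancels at rate
#' `C_r = alpha_c / (1 + (r / gamma_c)^epsilon_c)`, where `N` is group size
#' and `r` the number of departed individuals (initiator included).
#'
#' @param tau_o Initiation time constant (time units per attempt); the base
#'   initiation rate is `1/tau_o`.
#' @param alpha_f Following-rate offset (time units).
#' @param beta_f Following-rate group-composition coefficient (time units).
#' @param alpha_c Baseline cancellation rate (events per time unit).
#' @param gamma_c Cancellation half-saturation count (individuals).
#' @param epsilon_c Cancellation steepness exponent (dimensionless).
#' @param sigmoid_slope Slope constant of the LT-to-k sigmoid.
#' @param sigmoid_center Inflection point of the sigmoid; at
#'   `lt = sigmoid_center` the k factor is exactly half of `k_max`.
#' @param k_max Upper (non-inclusive) limit of the k factor. The default 2
#'   makes low and high LT values perturb the rates with equal magnitude,
#'   and `k = 1` (no change) at `lt = 0.5`.
#'
#' @return An object of class `lt_model_params`: a named list of the nine
#'   constants above.
#' @examples
#' p <- model_params()
#' k_factor(0.5, p) # exactly 1: the unmodified baseline model
#' @export
model_params <- function(tau_o = 1290,
                         alpha_f = 162.3,
                         beta_f = 75.4,
                         alpha_c = 0.009,
                         gamma_c = 2.0,
                         epsilon_c = 2.3,
                         sigmoid_slope = 10,
                         sigmoid_center = 0.5,
                         k_max = 2) {
  p <- list(
    tau_o = tau_o, alpha_f = alpha_f, beta_f = beta_f,
    alpha_c = alpha_c, gamma_c = gamma_c, epsilon_c = epsilon_c,
    sigmoid_slope = sigmoid_slope, sigmoid_center = sigmoid_center,
    k_max = k_max
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number.", call. = FALSE)
    }
  }
  for (nm in c("tau_o", "alpha_f", "beta_f", "alpha_c", "gamma_c", "k_max")) {
    if (p[[nm]] <= 0) stop("`", nm, "` must be strictly positive.", call. = FALSE)
  }
  if (p$sigmoid_center <= 0 || p$sigmoid_center >= 1) {
    stop("`sigmoid_center` must lie in (0, 1).", call. = FALSE)
  }
  structure(p, class = "lt_model_params")
}

#' Adaptation parameters for leadership tendencies
#'
#' Constructs the parameters of the linear reinforcement rule that updates
#' an initiator's leadership tendency (LT) after every attempt:
#' `L' = L * (1 - lambda) + lambda * r`, where the reinforcement `r` is
#' `reward_success` after a successful attempt and `reward_failure` after a
#' cancelled one. Updates exceeding `[lt_min, lt_max]` are truncated to the
#' bound; the restricted range keeps the k factor away from its
#' divide-by-zero limits.
#'
#' @param lambda_rate Learning rate `lambda` in `[0, 1]`. Small values weight
#'   long-run success history; the default 0.02 changes LT by at most 2% of
#'   its distance to the reinforcement value per attempt.
#' @param lt_min,lt_max Truncation bounds for LT (defaults 0.1 and 0.9).
#' @param reward_success,reward_failure Reinforcement values applied after a
#'   successful / failed attempt (defaults 1 and 0, symmetric about the
#'   sigmoid center so neither outcome is intrinsically favoured).
#' @param adaptive If `FALSE`, LT values are fixed for the whole run (the
#'   fixed-LT control mode); no reinforcement updates are applied.
#'
#' @return An object of class `lt_adapt_params`.
#' @examples
#' a <- adapt_params()
#' update_lt(0.5, success = TRUE, a) # 0.51
#' @export
adapt_params <- function(lambda_rate = 0.02,
                         lt_min = 0.1,
                         lt_max = 0.9,
                         reward_success = 1,
                         reward_failure = 0,
                         adaptive = TRUE) {
  stopifnot(is.numeric(lambda_rate), length(lambda_rate) == 1L)
  if (lambda_rate < 0 || lambda_rate > 1) {
    stop("`lambda_rate` must lie in [0, 1].", call. = FALSE)
  }
  if (!(lt_min > 0 && lt_min < lt_max && lt_max < 1)) {
    stop("need 0 < lt_min < lt_max < 1.", call. = FALSE)
  }
  if (!is.logical(adaptive) || length(adaptive) != 1L || is.na(adaptive)) {
    stop("`adaptive` must be TRUE or FALSE.", call. = FALSE)
  }
  structure(
    list(
      lambda_rate = lambda_rate, lt_min = lt_min, lt_max = lt_max,
      reward_success = reward_success, reward_failure = reward_failure,
      adaptive = adaptive
    ),
    class = "lt_adapt_params"
  )
}

#' @export
print.lt_model_params <- function(x, ...) {
  cat("<lt_model_params>\n")
  cat(sprintf(
    "  initiation: tau_o = %g\n  following:  alpha_f = %g, beta_f = %g\n",
    x$tau_o, x$alpha_f, x$beta_f
  ))
  cat(sprintf(
    "  canceling:  alpha_c = %g, gamma_c = %g, epsilon_c = %g\n",
    x$alpha_c, x$gamma_c, x$epsilon_c
  ))
  cat(sprintf(
    "  k sigmoid:  center = %g, slope = %g, k_max = %g\n",
    x$sigmoid_center, x$sigmoid_slope, x$k_max
  ))
  invisible(x)
}

#' @export
print.lt_adapt_params <- function(x, ...) {
  cat("<lt_adapt_params>\n")
  cat(sprintf(
    "  lambda = %g, bounds = [%g, %g], rewards = (%g success, %g failure), adaptive = %s\n",
    x$lambda_rate, x$lt_min, x$lt_max,
    x$reward_success, x$reward_failure, x$adaptive
  ))
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "lt_model_params")) return(x)
  do.call(model_params, as.list(x))
}

as_adapt_params <- function(x) {
  if (inherits(x, "lt_adapt_params")) return(x)
  do.call(adapt_params, as.list(x))
}
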