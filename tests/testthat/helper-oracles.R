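# Independent oracles kept deliberately separate from the package internals.

# Gillespie direct-method simulation of one movement attempt: at each stage
# the total event rate is the sum of all active clocks and the winning event
# is chosen with probability proportional to its rate. By memorylessness this
# has the same law as the package's redraw engine.
gillespie_attempt <- function(lt, params = model_params(),
                              adapt = adapt_params(adaptive = FALSE)) {
  n <- length(lt)
  k_of <- function(x) {
    params$k_max / (1 + exp((params$sigmoid_center - x) * params$sigmoid_slope))
  }
  init_rates <- k_of(lt) / params$tau_o
  init_id <- sample.int(n, 1, prob = init_rates)
  departed <- rep(FALSE, n)
  departed[init_id] <- TRUE
  repeat {
    r <- sum(departed)
    if (r == n) {
      return(TRUE)
    }
    cand <- which(!departed)
    base_tau <- params$alpha_f + params$beta_f * (n - r) / r
    follow_rates <- k_of(1 - lt[cand]) / base_tau
    c_rate <- k_of(1 - lt[init_id]) * params$alpha_c /
      (1 + (r / params$gamma_c)^params$epsilon_c)
    pick <- sample.int(length(cand) + 1L, 1, prob = c(follow_rates, c_rate))
    if (pick > length(cand)) {
      return(FALSE)
    }
    departed[cand[pick]] <- TRUE
  }
}

# Closed-form success probability of one attempt for a uniform-LT group:
# the product over departed counts r of P(next event is a follow).
chain_success_probability <- function(n, params = model_params()) {
  p <- 1
  for (r in seq_len(n - 1)) {
    f <- (n - r) / (params$alpha_f + params$beta_f * (n - r) / r)
    cc <- params$alpha_c / (1 + (r / params$gamma_c)^params$epsilon_c)
    p <- p * f / (f + cc)
  }
  p
}

# Exhaustive least-squares segmentation: enumerate every admissible break
# placement for an exact break count and return the minimum-RSS placement.
enum_segment <- function(y, n_breaks, min_seg) {
  n <- length(y)
  rss <- function(i, j) {
    s <- y[i:j]
    sum((s - mean(s))^2)
  }
  best <- list(rss = Inf, breaks = integer(0))
  if (n_breaks == 0) {
    return(list(rss = rss(1, n), breaks = integer(0)))
  }
  positions <- seq.int(min_seg, n - min_seg)
  combos <- utils::combn(positions, n_breaks, simplify = FALSE)
  for (bp in combos) {
    lens <- diff(c(0, bp, n))
    if (any(lens < min_seg)) next
    bounds <- c(0, bp, n)
    tot <- 0
    for (s in seq_len(length(bounds) - 1)) {
      tot <- tot + rss(bounds[s] + 1, bounds[s + 1])
    }
    if (tot < best$rss) best <- list(rss = tot, breaks = bp)
  }
  best
}

# Textbook pooled two-sample t statistic, computed from first principles.
pooled_t_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Build an lt_evaluation with prescribed LT change records, for analysis
# tests that need trajectories with known shape.
synthetic_evaluation <- function(n_agents, n_attempts, changes,
                                 initial_lt = 0.5) {
  attempts <- data.frame(
    evaluation_id = 1L,
    attempt = seq_len(n_attempts),
    initiator_id = rep_len(seq_len(n_agents), n_attempts),
    success = 0L,
    final_departed = 1L
  )
  chg <- rbind(
    data.frame(
      agent_id = seq_len(n_agents), attempt = 0L, lt_value = initial_lt
    ),
    changes
  )
  evaluation_from_logs(attempts, chg,
    group_size = n_agents,
    initial_lt = initial_lt
  )
}
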