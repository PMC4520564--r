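test_that("event waiting times are exponential with the requested rate", {
  expect_error(draw_event_time(0), "strictly positive")
  expect_error(draw_event_time(-1), "strictly positive")
  set.seed(11)
  x1 <- draw_event_time(1)
  set.seed(11)
  expect_identical(draw_event_time(1), x1)
  set.seed(12)
  draws <- draw_event_time(2, n = 1e5)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
  set.seed(13)
  slow <- draw_event_time(0.009, n = 1e5)
  expect_lt(abs(mean(slow > log(2) / 0.009) - 0.5), 3 * 0.5 / sqrt(1e5))
})

test_that("the initiation competition favours agents in proportion to k", {
  set.seed(21)
  # identical agents: winner uniform over the group
  wins <- tabulate(
    replicate(4000, select_initiator(rep(0.5, 5))$initiator_id),
    nbins = 5
  )
  expect_gt(chisq.test(wins)$p.value, 0.01)
  # competing exponentials: P(high-LT agent wins) = k(0.9)/(k(0.9)+k(0.1))
  p_expected <- k_factor(0.9) / (k_factor(0.9) + k_factor(0.1))
  set.seed(22)
  w <- mean(replicate(4000, select_initiator(c(0.9, 0.1))$initiator_id) == 1)
  expect_lt(abs(w - p_expected), 3 * sqrt(p_expected * (1 - p_expected) / 4000))
})

test_that("a single attempt respects the event grammar", {
  set.seed(31)
  for (i in 1:50) {
    att <- simulate_attempt(runif(8, 0.1, 0.9))
    log <- att$event_log
    expect_equal(log$event[1], "initiate")
    expect_equal(sum(log$event == "initiate"), 1)
    expect_lte(sum(log$event == "follow"), 7)
    expect_lte(sum(log$event == "cancel"), 1)
    expect_true(all(diff(log$time) > 0))
    if (att$success) {
      expect_equal(sum(log$event == "follow"), 7)
      expect_equal(att$final_departed, 8)
      expect_equal(sum(log$event == "cancel"), 0)
    } else {
      expect_equal(log$event[nrow(log)], "cancel")
      expect_lt(att$final_departed, 8)
    }
  }
})

test_that("attempts always succeed when cancellation is impossible", {
  p <- model_params()
  p$alpha_c <- 1e-300 # cancellation effectively impossible
  set.seed(32)
  for (i in 1:20) {
    att <- simulate_attempt(rep(0.5, 6), params = p)
    expect_true(att$success)
    expect_equal(att$final_departed, 6)
  }
})

test_that("only the initiator's LT is updated, and only in adaptive mode", {
  set.seed(33)
  lt0 <- rep(0.5, 6)
  att <- simulate_attempt(lt0, adapt = adapt_params())
  expected <- if (att$success) 0.51 else 0.49
  expect_equal(att$lt[att$initiator_id], expected)
  expect_equal(att$lt[-att$initiator_id], lt0[-att$initiator_id])
  set.seed(33)
  fixed <- simulate_attempt(lt0, adapt = adapt_params(adaptive = FALSE))
  expect_equal(fixed$lt, lt0)
})

test_that("attempts are bit-identical under the same seed", {
  set.seed(41)
  a <- simulate_attempt(c(0.3, 0.5, 0.7, 0.9))
  set.seed(41)
  b <- simulate_attempt(c(0.3, 0.5, 0.7, 0.9))
  expect_identical(a, b)
  expect_error(simulate_attempt(0.5), "at least 2")
})

test_that("the first post-initiation event is a follow with the closed-form probability", {
  # all-moderate group of 10: (9/840.9) vs cancel 0.009/(1 + 0.5^2.3)
  f <- 9 / 840.9
  cc <- 0.009 / (1 + 0.5^2.3)
  p_follow <- f / (f + cc)
  cfg <- evaluation_config(
    group_size = 10, initial_lt = 0.5, attempts_multiplier = 3000,
    adapt = adapt_params(adaptive = FALSE), seed = 5L
  )
  ev <- run_evaluation(cfg, 1)
  # attempts whose first event was a cancel end with exactly 1 departed
  first_follow <- mean(ev$attempts$final_departed > 1)
  n <- nrow(ev$attempts)
  expect_lt(abs(first_follow - p_follow), 3 * sqrt(p_follow * (1 - p_follow) / n))
})

test_that("the redraw engine agrees with a Gillespie direct-method oracle", {
  # same event law by memorylessness; compare success probabilities
  n_try <- 6000
  set.seed(51)
  oracle <- mean(replicate(n_try, gillespie_attempt(rep(0.5, 10))))
  cfg <- evaluation_config(
    group_size = 10, initial_lt = 0.5,
    attempts_multiplier = ceiling(n_try / 10),
    adapt = adapt_params(adaptive = FALSE), seed = 6L
  )
  engine <- mean(run_evaluation(cfg, 1)$attempts$success)
  closed <- chain_success_probability(10)
  se <- sqrt(closed * (1 - closed) / n_try)
  expect_lt(abs(engine - oracle), 3 * sqrt(2) * se)
  expect_lt(abs(engine - closed), 3 * se)
  expect_lt(abs(oracle - closed), 3 * se)
})

test_that("the R reference attempt and the compiled engine share one law", {
  # compare success probability and mean departed count at mixed LTs
  lt <- c(0.9, 0.9, rep(0.2, 8))
  set.seed(61)
  ref <- replicate(4000, {
    a <- simulate_attempt(lt, adapt = adapt_params(adaptive = FALSE))
    c(a$success, a$final_departed)
  })
  cfg_lt <- rep(NA, 0) # engine path: fixed LTs via adaptive = FALSE
  set.seed(62)
  raw <- leadsim:::run_attempts_cpp(
    10, 4000, lt, unclass(model_params()),
    unclass(adapt_params(adaptive = FALSE)),
    record_events = FALSE
  )
  p1 <- mean(ref[1, ])
  p2 <- mean(raw$success)
  se <- sqrt(p1 * (1 - p1) / 4000)
  expect_lt(abs(p1 - p2), 3 * sqrt(2) * se)
  m1 <- mean(ref[2, ])
  m2 <- mean(raw$final_departed)
  expect_lt(abs(m1 - m2), 3 * sqrt(2) * sd(ref[2, ]) / sqrt(4000))
})
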