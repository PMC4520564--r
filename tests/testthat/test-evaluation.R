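test_that("seed derivation is deterministic, in range, and replicate-driven", {
  expect_identical(derive_seed(1, 1), derive_seed(1, 1))
  s <- vapply(1:200, function(r) derive_seed(123, r), integer(1))
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_equal(length(unique(s)), 200)
  expect_false(derive_seed(1, 1) == derive_seed(2, 1))
})

test_that("an evaluation produces the configured number of attempt records", {
  cfg <- evaluation_config(
    group_size = 10, initial_lt = 0.5, attempts_multiplier = 10,
    adapt = adapt_params(adaptive = FALSE)
  )
  ev <- run_evaluation(cfg, 1)
  expect_equal(nrow(ev$attempts), 100)
  expect_identical(ev$attempts$attempt, 1:100)
  # fixed-LT mode: no change records beyond the initial values
  expect_equal(nrow(ev$lt_changes), 10)
  expect_true(all(ev$lt_changes$attempt == 0))
  expect_equal(ev$final_lt, rep(0.5, 10))
  hist <- lt_history(ev)
  expect_equal(nrow(hist), 1000)
  expect_true(all(hist$lt_value == 0.5))
})

test_that("lambda = 0 with adaptation on behaves as the fixed-LT control", {
  cfg0 <- evaluation_config(
    group_size = 6, attempts_multiplier = 50,
    adapt = adapt_params(lambda_rate = 0, adaptive = TRUE)
  )
  cfg_off <- evaluation_config(
    group_size = 6, attempts_multiplier = 50,
    adapt = adapt_params(adaptive = FALSE)
  )
  ev0 <- run_evaluation(cfg0, 1)
  ev_off <- run_evaluation(cfg_off, 1)
  expect_identical(ev0$attempts, ev_off$attempts)
  expect_equal(ev0$final_lt, rep(0.5, 6))
})

test_that("LT values change only at attempts the agent initiated", {
  cfg <- evaluation_config(group_size = 8, initial_lt = 0.5, attempts_multiplier = 100)
  ev <- run_evaluation(cfg, 2)
  chg <- ev$lt_changes[ev$lt_changes$attempt > 0, ]
  expect_gt(nrow(chg), 0)
  init_of <- ev$attempts$initiator_id[chg$attempt]
  expect_equal(chg$agent_id, init_of)
  # change records match the reinforcement rule applied to the prior value
  hist <- lt_history(ev)
  for (i in seq_len(nrow(chg))) {
    at <- chg$attempt[i]
    id <- chg$agent_id[i]
    before <- hist$lt_value[hist$agent_id == id & hist$attempt == at]
    ok <- ev$attempts$success[at]
    expect_equal(chg$lt_value[i], update_lt(before, ok, cfg$adapt))
  }
  expect_true(all(hist$lt_value >= 0.1 & hist$lt_value <= 0.9))
})

test_that("evaluations are reproducible and differ across replicates", {
  cfg <- evaluation_config(group_size = 6, attempts_multiplier = 50)
  a <- run_evaluation(cfg, 3)
  b <- run_evaluation(cfg, 3)
  expect_identical(a$attempts, b$attempts)
  expect_identical(a$lt_changes, b$lt_changes)
  c2 <- run_evaluation(cfg, 4)
  expect_false(identical(a$attempts, c2$attempts))
})

test_that("the treatment grid shares replicate seeds across cells", {
  grid <- run_treatment_grid(
    group_sizes = c(6, 8), initial_lts = c(0.2, 0.8),
    attempts_multiplier = 5, replicate_count = 2, seed = 9L, quiet = TRUE
  )
  expect_equal(nrow(grid), 8)
  by_rep <- split(grid$seed_used, grid$replicate)
  for (s in by_rep) expect_equal(length(unique(s)), 1)
  expect_false(by_rep[[1]][1] == by_rep[[2]][1])
})

test_that("an adaptive small-group evaluation differentiates to the bounds", {
  cfg <- evaluation_config(group_size = 10, initial_lt = 0.5, attempts_multiplier = 2000)
  ev <- run_evaluation(cfg, 1)
  expect_gte(max(ev$final_lt), 0.85)
  expect_lte(min(ev$final_lt), 0.15)
  # leaders dominate initiations once differentiated
  late <- ev$attempts[ev$attempts$attempt > 15000, ]
  high_agents <- which(ev$final_lt > 0.8)
  expect_gt(mean(late$initiator_id %in% high_agents), 0.5)
})

test_that("success probability grows with group size for moderate fixed groups", {
  ps <- vapply(c(10, 30, 60), function(n) {
    cfg <- evaluation_config(
      group_size = n, initial_lt = 0.5,
      attempts_multiplier = max(2, ceiling(3000 / n)),
      adapt = adapt_params(adaptive = FALSE), seed = 7L
    )
    mean(run_evaluation(cfg, 1)$attempts$success)
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
  # and matches the closed-form chain probability at each size
  for (i in seq_along(ps)) {
    closed <- chain_success_probability(c(10, 30, 60)[i])
    expect_lt(abs(ps[i] - closed), 4 * sqrt(closed * (1 - closed) / 3000))
  }
})
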