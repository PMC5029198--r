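test_that("the 3-down/1-up update rule moves, reverses and halves correctly", {
  cfg <- staircase_config(total_elements = 200,
                          initial_level_elements = 64,
                          initial_step_elements = 16)
  st <- new_staircase(cfg)
  # two correct responses leave the level alone, the third lowers it
  st <- update_staircase(st, cfg, TRUE)
  st <- update_staircase(st, cfg, TRUE)
  expect_equal(st$level, 64)
  st <- update_staircase(st, cfg, TRUE)
  expect_equal(st$level, 48)
  expect_equal(st$n_correct, 0)
  expect_length(st$reversal_levels, 0)
  # an error after a descent records a reversal and halves the step
  st <- update_staircase(st, cfg, FALSE)
  expect_equal(st$reversal_levels, 48)
  expect_equal(st$reversal_steps, 16)
  expect_equal(st$step, 8)
  expect_equal(st$level, 56)
  # a further error continues upward without a reversal
  st <- update_staircase(st, cfg, FALSE)
  expect_equal(st$level, 64)
  expect_length(st$reversal_levels, 1)
})

test_that("termination requires six floor-step reversals and locks the state", {
  cfg <- staircase_config(total_elements = 8,
                          initial_level_elements = 4,
                          initial_step_elements = 1)
  st <- new_staircase(cfg)
  # alternate triple-correct / error to generate step-1 reversals
  n_rev <- 0
  while (!st$terminated) {
    st <- update_staircase(st, cfg, TRUE)
    st <- update_staircase(st, cfg, TRUE)
    st <- update_staircase(st, cfg, TRUE)
    if (st$terminated) break
    st <- update_staircase(st, cfg, FALSE)
  }
  expect_true(st$terminated)
  expect_equal(sum(st$reversal_steps == 1), 6)
  expect_error(update_staircase(st, cfg, TRUE), "terminated")
})

test_that("threshold estimates average the last six reversal levels", {
  cfg <- staircase_config(total_elements = 200)
  st <- new_staircase(cfg)
  st$reversal_levels <- c(20, 14, 18, 12, 16, 10)
  st$reversal_steps <- rep(1L, 6)
  st$terminated <- TRUE
  expect_equal(estimate_threshold(st, cfg), 100 * 15 / 200)
  expect_equal(estimate_threshold(st, cfg, use = "floor"), 7.5)
  # constant reversal level is returned exactly
  st$reversal_levels <- rep(30, 6)
  expect_equal(estimate_threshold(st, cfg), 15)
  st$terminated <- FALSE
  expect_error(estimate_threshold(st, cfg), "termination")
})

test_that("a deterministic step observer is recovered to within one element", {
  cfg <- staircase_config(total_elements = 200)
  st <- run_staircase(step_observer(40, 200), cfg, seed = 1)
  est_elements <- estimate_threshold(st, cfg) * 200 / 100
  expect_lte(abs(est_elements - 40), 1)
  # the two estimate readings coincide under the default termination rule
  expect_equal(estimate_threshold(st, cfg),
               estimate_threshold(st, cfg, use = "floor"))
})

test_that("degenerate observers drive the staircase to the expected extremes", {
  cfg <- staircase_config(total_elements = 200)
  # near-perfect observer: floor region, tiny estimate
  sharp <- psychometric_observer(0.5, slope = 8, lapse_rate = 0)
  ests <- vapply(1:20, function(s) {
    estimate_threshold(run_staircase(sharp, cfg, seed = s), cfg)
  }, numeric(1))
  expect_lte(mean(ests), 100 * 3 / 200)
  # uninformative observer: estimates sit far above 50% coherence
  flat <- psychometric_observer(100, slope = 8, lapse_rate = 0.05)
  expect_lt(max(prob_correct(flat, c(0, 25, 50, 75))), 0.55)
  ests0 <- vapply(1:60, function(s) {
    estimate_threshold(run_staircase(flat, cfg, seed = 100 + s), cfg)
  }, numeric(1))
  expect_gt(mean(ests0), 50)
})

test_that("staircase runs are reproducible and respect the trial cap", {
  cfg <- staircase_config(total_elements = 200)
  obs <- psychometric_observer(20)
  a <- run_staircase(obs, cfg, seed = 5)
  b <- run_staircase(obs, cfg, seed = 5)
  expect_identical(a$trial_levels, b$trial_levels)
  expect_identical(a$trial_correct, b$trial_correct)
  # an always-correct responder never reverses: the guard must fire
  tiny <- staircase_config(total_elements = 8, max_trials = 200)
  expect_error(run_staircase(function(c) TRUE, tiny, seed = 1),
               "failed to terminate")
})

test_that("sessions average at least four staircases and shrink variance", {
  cfg <- staircase_config(total_elements = 200)
  obs <- psychometric_observer(15)
  expect_error(run_session(obs, cfg, n_staircases = 3, seed = 1),
               "four")
  ses <- run_session(obs, cfg, n_staircases = 4, seed = 2,
                     keep_states = TRUE)
  expect_equal(ses$session_threshold_pct, mean(ses$staircase_thresholds))
  expect_length(ses$staircase_thresholds, 4)
  # variance of the session mean is below single-staircase variance
  singles <- vapply(1:60, function(s) {
    estimate_threshold(run_staircase(obs, cfg, seed = 200 + s), cfg)
  }, numeric(1))
  sessions <- vapply(1:30, function(s) {
    run_session(obs, cfg, seed = 400 + s)$session_threshold_pct
  }, numeric(1))
  expect_lt(var(sessions), var(singles))
})

test_that("a staircase can be driven by full stimulus generation", {
  cfg <- staircase_config(total_elements = 200, max_trials = 2000)
  obs <- stimulus_observer("rdk_motion", internal_noise_sd = 0.3)
  st <- run_staircase(obs, cfg, seed = 9)
  expect_true(st$terminated)
  est <- estimate_threshold(st, cfg)
  expect_gt(est, 0)
  expect_lte(est, 100)
})
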