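test_that("reversal detection applies the switch rule", {
  expect_equal(detect_reversals(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)),
               c(3L, 4L, 5L, 7L))
  expect_equal(detect_reversals(rep(TRUE, 4)), integer(0))
  expect_equal(detect_reversals(c(TRUE, FALSE, TRUE, FALSE, TRUE)), 2:5)
  expect_equal(detect_reversals(FALSE), integer(0))
})

test_that("the up-down rule moves and clamps the difference", {
  cfg <- pitch_staircase_config()
  expect_equal(next_delta(100, correct = TRUE, phase = 1, cfg), 90)
  expect_equal(next_delta(100, correct = FALSE, phase = 1, cfg), 130)
  expect_equal(next_delta(100, correct = TRUE, phase = 2, cfg), 98)
  expect_equal(next_delta(100, correct = FALSE, phase = 2, cfg), 106)
  expect_equal(next_delta(1, correct = TRUE, phase = 2, cfg), 1)      # floor
  expect_equal(next_delta(2395, correct = FALSE, phase = 1, cfg), 2400)  # ceiling
  tcfg <- timbre_staircase_config()
  expect_equal(next_delta(12, FALSE, 1, tcfg), 15)
  expect_equal(next_delta(12, TRUE, 1, tcfg), 11)
  expect_equal(next_delta(2, TRUE, 2, tcfg), 1.8)
})

test_that("step-size invariants are enforced at construction", {
  expect_error(staircase_config(100, 10, 30, 6, 2, delta_floor = 1,
                                delta_ceiling = 2400))   # up must exceed down
  expect_error(staircase_config(100, 30, 10, 6, 2, delta_floor = 10,
                                delta_ceiling = 5))
})

test_that("an always-correct observer descends to the floor and trips the cap", {
  cfg <- staircase_config(100, 30, 10, 6, 2, delta_floor = 1,
                          delta_ceiling = 2400, max_trials = 500)
  always <- sigmoid_observer(1e-6, slope = 50, lapse = 0)
  expect_error(run_staircase(always, cfg, seed = 1),
               class = "voxpitch_nonconvergence")
})

test_that("a deterministic threshold observer oscillates around its step", {
  obs <- threshold_observer(50)
  run <- run_staircase(obs, pitch_staircase_config(), seed = 2)
  expect_equal(sum(run$trials$is_reversal), 14)
  # hand-derivable track: 100, 90, ... down in 10s while >= 50, then up 30
  expect_equal(run$trials$delta[1:7], c(100, 90, 80, 70, 60, 50, 40))
  expect_false(run$trials$correct[7])   # 40 < 50
  expect_true(run$jnd >= min(run$reversal_deltas) &&
                run$jnd <= max(run$reversal_deltas))
  expect_true(min(run$reversal_deltas) <= 50 && max(run$reversal_deltas) >= 50)
})

test_that("phase switches after the configured reversal count", {
  obs <- sigmoid_observer(40, slope = 8, lapse = 0.02)
  run <- run_staircase(obs, pitch_staircase_config(), seed = 7)
  tr <- run$trials
  fourth <- which(tr$is_reversal)[4]
  expect_true(all(tr$phase[1:fourth] == 1))
  expect_true(all(tr$phase[(fourth + 1):nrow(tr)] == 2))
  # step magnitude after the switch is the phase-2 step
  post <- (fourth + 1):(nrow(tr) - 1)
  steps <- abs(diff(tr$delta))[post]
  expect_true(all(steps %in% c(2, 6, 0)))  # 0 only if clamped
})

test_that("runs are bit-reproducible under a fixed seed", {
  obs <- sigmoid_observer(40, slope = 8, lapse = 0.02)
  r1 <- run_staircase(obs, pitch_staircase_config(), seed = 11)
  r2 <- run_staircase(obs, pitch_staircase_config(), seed = 11)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$jnd, r2$jnd)
  t1 <- run_test(obs, pitch_staircase_config(), n_runs = 5, seed = 4)
  t2 <- run_test(obs, pitch_staircase_config(), n_runs = 5, seed = 4)
  expect_identical(t1$jnds, t2$jnds)
  expect_equal(t1$jnd_mean, mean(t1$jnds))
  expect_length(t1$run_results, 5)
})

test_that("the JND estimator equals an independent reversal-scan oracle", {
  obs <- sigmoid_observer(40, slope = 8, lapse = 0.02)
  for (seed in 1:20) {
    run <- run_staircase(obs, pitch_staircase_config(), seed = seed)
    expect_equal(run$jnd, oracle_jnd(run$trials))
    expect_equal(estimate_jnd(run), run$jnd)
    # re-estimating from the bare trial log (reversals re-derived) agrees
    expect_equal(estimate_jnd(run$trials[, c("delta", "correct")],
                              config = pitch_staircase_config()), run$jnd)
  }
})

test_that("mean of explicitly given reversal deltas is the arithmetic mean", {
  deltas <- c(40, 60, 38, 58, 40, 56, 42, 54, 44, 52)
  expect_equal(mean(deltas), 48.4)
  # constant-track case: every reversal delta equal gives that value
  cfg <- staircase_config(50, 30, 10, 6, 2, delta_floor = 50,
                          delta_ceiling = 50.0001)
  obs <- sigmoid_observer(50, slope = 8, lapse = 0.5)
  run <- run_staircase(obs, cfg, seed = 3)
  expect_equal(run$jnd, 50, tolerance = 1e-6)
})

test_that("too few reversals yields an insufficient-data error", {
  trials <- data.frame(delta = c(100, 90, 80, 120, 110),
                       correct = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(estimate_jnd(trials, config = pitch_staircase_config()),
               class = "voxpitch_insufficient_data")
})

test_that("staircases converge to the 75% point on both scales", {
  # moderate replication here; the full-precision check lives in the
  # acceptance suite
  n <- 300
  obs <- sigmoid_observer(40, slope = 8, lapse = 0.02)
  tgt <- threshold_at(obs, 0.75)
  set.seed(5)
  jnds <- replicate(n, run_staircase(obs, pitch_staircase_config())$jnd)
  expect_lt(abs(mean(jnds) - tgt), 4 * sd(jnds) / sqrt(n))
  tobs <- sigmoid_observer(4, slope = 8, lapse = 0.02)
  ttgt <- threshold_at(tobs, 0.75)
  tj <- replicate(n, run_staircase(tobs, timbre_staircase_config())$jnd)
  expect_lt(abs(mean(tj) - ttgt), 4 * sd(tj) / sqrt(n))
})

test_that("interval order is balanced and correctness follows the task rule", {
  obs <- sigmoid_observer(40, slope = 8, lapse = 0.02)
  set.seed(6)
  tr <- do.call(rbind, lapply(1:30, function(i)
    run_staircase(obs, pitch_staircase_config())$trials))
  expect_true(all(tr$correct == (tr$response == tr$order)))
  frac1 <- mean(tr$order == 1)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})
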