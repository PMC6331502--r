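test_that("default cohorts satisfy the matched-pair design invariants", {
  spec <- cohort_spec()
  co <- generate_cohort(spec, seed = 11)
  expect_equal(nrow(co), 32)
  expect_equal(sum(co$group == "asd"), 16)
  expect_equal(sum(co$group == "comparison"), 16)
  wide <- merge(co[co$group == "asd", c("pair_id", "age", "iq_full",
                                        "gender", "handedness")],
                co[co$group == "comparison", c("pair_id", "age", "iq_full",
                                               "gender", "handedness")],
                by = "pair_id", suffixes = c("_asd", "_comp"))
  expect_true(all(abs(wide$age_asd - wide$age_comp) <= 3))
  expect_true(all(abs(wide$iq_full_asd - wide$iq_full_comp) <= 15))
  expect_equal(wide$gender_asd, wide$gender_comp)
  expect_equal(wide$handedness_asd, wide$handedness_comp)
  expect_equal(sum(co$gender == "female"), 2 * 3)
  expect_equal(sum(co$handedness == "left"), 2 * 2)
  # bounded scales and screening
  expect_true(all(co$aq >= 0 & co$aq <= 50))
  expect_true(all(co$aq[co$group == "comparison"] < 32))
  expect_true(all(co$pitch_jnd > 0 & co$timbre_jnd > 0))
  emo_cols <- paste0("emotion_", EMOTIONS)
  expect_true(all(co[, emo_cols] >= 0 & co[, emo_cols] <= 100))
  expect_equal(co$emotion_total, rowMeans(co[, emo_cols]))
  expect_true(all(is.na(co$ados_comm[co$group == "comparison"])))
  expect_true(all(co$ados_comm[co$group == "asd"] > 0))
})

test_that("cohort generation is reproducible under seed", {
  a <- generate_cohort(seed = 99)
  b <- generate_cohort(seed = 99)
  expect_identical(a, b)
  c <- generate_cohort(seed = 100)
  expect_false(identical(a$pitch_jnd, c$pitch_jnd))
})

test_that("marginal transforms hit their target moments exactly", {
  # quadrature check of the moment matching that underlies the generator:
  # simulate a very large latent sample through each documented marginal
  set.seed(12)
  z <- rnorm(4e5)
  tr <- voxpitch:::make_logit_transform(51.45, 32.05, 100)
  v <- tr$g(z)
  expect_lt(abs(mean(v) - 51.45), 0.2)
  expect_lt(abs(sd(v) - 32.05), 0.2)
  tr2 <- voxpitch:::make_lognormal_transform(65.18, 47.69)
  v2 <- tr2$g(z)
  expect_lt(abs(mean(v2) - 65.18) / 65.18, 0.01)
  expect_lt(abs(sd(v2) - 47.69) / 47.69, 0.015)
})

test_that("large cohorts recover the correlation targets", {
  co <- generate_cohort(cohort_spec(n_pairs = 2000), seed = 13)
  comp <- co[co$group == "comparison", ]
  asd <- co[co$group == "asd", ]
  expect_lt(abs(cor(comp$emotion_total, comp$pitch_jnd) - (-0.554)), 0.07)
  expect_lt(abs(cor(asd$emotion_total, asd$pitch_jnd) - (-0.346)), 0.07)
  expect_lt(abs(cor(asd$emotion_total, asd$ados_comm) - (-0.672)), 0.07)
  # untargeted pairings stay near zero
  expect_lt(abs(cor(comp$emotion_total, comp$timbre_jnd)), 0.1)
})

test_that("a zero-correlation spec gives near-independent measures", {
  spec <- cohort_spec(n_pairs = 400, correlations = list(
    asd = c(pitch_jnd = 0, timbre_jnd = 0, nonvocal_pitch = 0, aq = 0,
            ados_comm = 0),
    comparison = c(pitch_jnd = 0, timbre_jnd = 0, nonvocal_pitch = 0, aq = 0,
                   ados_comm = NA)))
  co <- generate_cohort(spec, seed = 14)
  comp <- co[co$group == "comparison", ]
  se <- 1 / sqrt(nrow(comp))
  expect_lt(abs(cor(comp$emotion_total, comp$pitch_jnd)), 4 * se)
  expect_lt(abs(cor(comp$emotion_total, comp$aq)), 4 * se)
})

test_that("emotion sessions recover the generating profile in expectation", {
  prof <- stats::setNames(c(100, 100, 100, 100, 100, 100), EMOTIONS)
  sess <- generate_emotion_session(prof, seed = 15)
  expect_true(validate_design(sess)$valid)
  expect_equal(score_session(sess)$total_accuracy, 100)

  prof2 <- stats::setNames(c(64.10, 51.45, 68.37, 84.98, 50.18, 90.63),
                           EMOTIONS)
  set.seed(16)
  totals <- replicate(500, score_session(generate_emotion_session(prof2))$total_accuracy)
  sem <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - mean(prof2)), 3 * sem)
})

test_that("a supplied confusion kernel steers error responses", {
  prof <- stats::setNames(rep(0, 6), EMOTIONS)   # always wrong
  kernel <- matrix(0, 6, 6, dimnames = list(EMOTIONS, EMOTIONS))
  kernel["happiness", "neutral"] <- 1            # happy words misheard as neutral
  kernel[kernel == 0] <- 1e-12
  sess <- generate_emotion_session(prof, seed = 17, confusion_kernel = kernel)
  resp <- sess$response_emotion[sess$true_emotion == "happiness"]
  expect_true(all(resp == "neutral"))
})

test_that("derived observers place their 75% point at the generated JND", {
  co <- generate_cohort(seed = 18)
  obs <- generate_staircase_observers(co, scale = "pitch")
  p75 <- vapply(obs, threshold_at, numeric(1), p = 0.75)
  expect_equal(unname(p75), co$pitch_jnd, tolerance = 1e-9)
  # table-anchored fixture values round-trip too
  fix <- data.frame(id = c("comp_mean", "asd_mean"),
                    pitch_jnd = c(36.02, 65.18))
  obs2 <- generate_staircase_observers(fix, scale = "pitch")
  expect_equal(threshold_at(obs2[["comp_mean"]], 0.75), 36.02)
  expect_equal(threshold_at(obs2[["asd_mean"]], 0.75), 65.18)
})
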