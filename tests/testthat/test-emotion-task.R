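test_that("the canonical 120-trial design validates and violations are caught", {
  sess <- perfect_session()
  report <- validate_design(sess)
  expect_true(report$valid)
  expect_true(all(report$emotion_counts == 20))
  expect_true(all(report$cell_counts == 10))

  short <- sess[-1, ]
  expect_false(validate_design(short)$valid)
  expect_match(paste(validate_design(short)$violations, collapse = " "), "119")

  skew <- sess
  skew$speaker[skew$true_emotion == "fear"] <- "female"
  rep2 <- validate_design(skew)
  expect_false(rep2$valid)
  expect_match(paste(rep2$violations, collapse = " "), "speaker")
})

test_that("scoring a perfect session gives 100% and an identity confusion", {
  s <- score_session(perfect_session())
  expect_equal(s$total_accuracy, 100)
  expect_equal(unname(s$per_emotion_accuracy), rep(100, 6))
  expect_equal(unname(diag(s$confusion)), rep(100, 6))
  expect_equal(unname(rowSums(s$confusion)), rep(100, 6))
})

test_that("confusion rows are distributions and total is the weighted mean", {
  set.seed(21)
  prof <- stats::setNames(c(64, 51, 68, 85, 50, 91), EMOTIONS)
  sess <- generate_emotion_session(prof)
  s <- score_session(sess)
  expect_equal(unname(rowSums(s$confusion)), rep(100, 6), tolerance = 1e-9)
  expect_equal(s$total_accuracy, mean(s$per_emotion_accuracy))  # equal counts
  expect_equal(unname(diag(s$confusion)), unname(s$per_emotion_accuracy))
})

test_that("random responding scores at the 1/6 chance level", {
  set.seed(22)
  prof <- stats::setNames(rep(100 / 6, 6), EMOTIONS)
  totals <- replicate(400, score_session(generate_emotion_session(prof))$total_accuracy)
  sem <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 100 / 6), 3 * sem)
})

test_that("scoring rejects malformed sessions unless overridden", {
  sess <- perfect_session()[seq(1, 120, by = 2), ]   # 10 trials per emotion
  expect_error(score_session(sess), class = "voxpitch_invalid_design")
  s <- score_session(sess, check_design = FALSE)
  expect_equal(s$total_accuracy, 100)
  expect_equal(s$n_trials, 60)
})

test_that("quartile binning splits 120 distinct values into 30 per level", {
  sess <- perfect_session()
  sess$intensity_score <- seq_len(120)
  lv <- bin_levels(sess, "intensity")
  expect_equal(as.vector(table(lv)), rep(30, 4))
  expect_equal(levels(lv), c("very low", "low", "high", "very high"))
  # assignment is monotone in the underlying value
  expect_true(all(diff(as.integer(lv[order(sess$intensity_score)])) >= 0))
  # ties straddling a boundary are resolved by stable id order
  sess$intensity_score <- rep(1:2, each = 60)
  lv2 <- bin_levels(sess, "intensity")
  expect_equal(as.vector(table(lv2)), rep(30, 4))
  sess$intensity_score <- rep(1, 120)
  expect_error(bin_levels(sess, "intensity"),
               class = "voxpitch_degenerate_binning")
})

test_that("a monotone intensity effect yields monotone level accuracies", {
  set.seed(23)
  attrs <- generate_stimulus_attributes()
  # a common intensity distribution across emotions, so the quartile levels
  # align with the within-emotion difficulty the generator acts on
  attrs$intensity_score <- rnorm(120)
  prof <- stats::setNames(rep(70, 6), EMOTIONS)
  acc <- matrix(0, 40, 4)
  for (i in 1:40) {
    sess <- generate_emotion_session(prof, stimulus_attributes = attrs,
                                     intensity_effect = 1.5)
    acc[i, ] <- level_accuracy(sess, bin_levels(sess, "intensity"))
  }
  means <- colMeans(acc)
  expect_true(all(diff(means) > 0))
})

test_that("level_anova delegates to the mixed ANOVA with 4 within levels", {
  set.seed(24)
  lm4 <- matrix(rnorm(32 * 4, mean = rep(c(60, 70, 80, 90), each = 32)), 32, 4)
  grp <- rep(c("asd", "comparison"), each = 16)
  res <- level_anova(lm4, grp)
  expect_s3_class(res, "mixed_anova")
  within <- res[res$effect == "within", ]
  expect_equal(within$df1, 3)
  expect_equal(within$df2, 28)   # N - groups - levels + 2 = 32 - 2 - 3 + 1
  expect_gt(within$F, 10)
  # identical levels within every subject: difference scores are singular
  flat <- matrix(rep(rnorm(32), 4), 32, 4)
  expect_error(level_anova(flat, grp), class = "voxpitch_rank_deficient")
})
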