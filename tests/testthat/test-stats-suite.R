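test_that("pooled t and d reproduce published group comparisons", {
  sadness <- pooled_t_and_d(81.64, 10.76, 16, 51.45, 32.05, 16)
  expect_lt(abs(sadness$t - 3.573), 0.002)
  expect_lt(abs(sadness$d - 1.263), 0.002)
  expect_equal(sadness$df, 30)
  fear <- pooled_t_and_d(89.85, 6.71, 16, 68.37, 27.82, 16)
  expect_lt(abs(fear$t - 3.002), 0.002)
  expect_lt(abs(fear$d - 1.061), 0.002)
  # identical groups
  eq <- pooled_t_and_d(10, 2, 8, 10, 2, 8)
  expect_equal(c(eq$t, eq$d), c(0, 0))
  expect_equal(eq$p, 1)
  # t/d consistency identity
  x <- pooled_t_and_d(5.3, 1.1, 12, 4.1, 2.3, 9)
  expect_equal(x$d, x$t * sqrt(1 / 12 + 1 / 9), tolerance = 1e-12)
  expect_equal(sign(x$t), sign(5.3 - 4.1))
  expect_error(pooled_t_and_d(1, 0, 5, 2, 0, 5),
               class = "voxpitch_infinite_statistic")
})

test_that("partial eta squared follows F df1 / (F df1 + df2)", {
  expect_lt(abs(eta_p2_from_F(11.594, 1, 30) - 0.279), 5e-4)
  expect_lt(abs(eta_p2_from_F(15.062, 5, 26) - 0.743), 5e-4)
  expect_lt(abs(eta_p2_from_F(2.346, 5, 26) - 0.311), 5e-4)
  expect_equal(eta_p2_from_F(0, 3, 28), 0)
})

test_that("mixed_anova matches the multivariate oracle on small instances", {
  set.seed(41)
  for (rep in 1:8) {
    N <- sample(c(6, 8), 1)
    p_lev <- sample(2:3, 1)
    y <- matrix(rnorm(N * p_lev, mean = rep(seq_len(p_lev), each = N)), N, p_lev)
    grp <- rep(c("a", "b"), each = N / 2)
    mine <- mixed_anova(y, grp)
    orc <- oracle_mlm(y, grp)
    for (eff in c("within", "interaction")) {
      row <- mine[mine$effect == eff, ]
      expect_equal(row$F, orc[[eff]]$F, tolerance = 1e-9)
      expect_equal(row$lambda, orc[[eff]]$lambda, tolerance = 1e-9)
      expect_equal(row$df1, orc[[eff]]$df1)
      expect_equal(row$df2, orc[[eff]]$df2)
      # eta_p2 = 1 - lambda = F df1/(F df1 + df2) for these one-df hypotheses
      expect_equal(row$eta_p2, 1 - row$lambda, tolerance = 1e-9)
      expect_equal(row$eta_p2, eta_p2_from_F(row$F, row$df1, row$df2),
                   tolerance = 1e-9)
    }
  }
})

test_that("mixed_anova dfs match the 2x6 design and between F equals t^2", {
  set.seed(42)
  y <- matrix(rnorm(32 * 6, mean = 80, sd = 10), 32, 6)
  grp <- rep(c("asd", "comparison"), each = 16)
  res <- mixed_anova(y, grp)
  expect_equal(res$df1, c(1, 5, 5))
  expect_equal(res$df2, c(30, 26, 26))
  sm <- rowMeans(y)
  tt <- pooled_t_and_d(mean(sm[1:16]), sd(sm[1:16]), 16,
                      mean(sm[17:32]), sd(sm[17:32]), 16)
  expect_equal(res$F[res$effect == "group"], tt$t^2, tolerance = 1e-9)
  # univariate secondary mode carries sphericity-corrected p-values
  uni <- mixed_anova(y, grp, method = "univariate")
  w <- uni[uni$effect == "within", ]
  expect_equal(w$df1, 5); expect_equal(w$df2, 150)
  expect_true(w$eps_gg > 1 / 5 && w$eps_gg <= 1)
  expect_true(w$eps_hf >= w$eps_gg || abs(w$eps_hf - w$eps_gg) < 1e-12)
  expect_equal(w$p_gg, pf(w$F, w$df1 * w$eps_gg, w$df2 * w$eps_gg,
                          lower.tail = FALSE))
})

test_that("correlation p-values use the t approximation on n - 2 df", {
  expect_lt(abs(r_to_p(-0.672, 15) - 0.006), 5e-4)
  expect_lt(abs(r_to_p(-0.489, 16, tails = 1) - 0.027), 5e-4)
  expect_lt(abs(r_to_p(-0.501, 16) - 0.048), 5e-4)
  expect_equal(r_to_p(1, 20), 0)
})

test_that("the Shapiro-Wilk gate selects Pearson or Spearman", {
  set.seed(43)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30, sd = 0.5)
  res <- correlation(x, y, gate = "auto")
  expect_equal(res$method, "pearson")
  expect_equal(res$r, cor(x, y))
  skew <- exp(rnorm(30, sd = 1.5))
  res2 <- correlation(x, skew, gate = "auto")
  expect_equal(res2$method, "spearman")
  expect_equal(res2$r, cor(x, skew, method = "spearman"))
  # forced methods override the gate
  expect_equal(correlation(x, skew, gate = "pearson")$method, "pearson")
  expect_error(correlation(x, rep(1, 30)),
               class = "voxpitch_undefined_correlation")
})

test_that("one-tailed p is halved only when the sign matches the direction", {
  set.seed(44)
  x <- rnorm(20); y <- -0.6 * x + rnorm(20, sd = 0.6)
  two <- correlation(x, y, tails = 2, gate = "pearson")
  match_dir <- correlation(x, y, tails = 1, gate = "pearson",
                           direction = "negative")
  mismatch <- correlation(x, y, tails = 1, gate = "pearson",
                          direction = "positive")
  expect_equal(match_dir$p, two$p / 2)
  expect_equal(mismatch$p, 1 - two$p / 2)
})

test_that("perfectly linear data give r = 1 and vanishing p", {
  x <- 1:10
  res <- correlation(x, 2 * x + 3, gate = "pearson")
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
})

test_that("Tukey fences flag gross outliers and spare uniform spread", {
  expect_equal(as.integer(tukey_outliers(c(1:8, 100))), 9L)
  expect_length(tukey_outliers(seq(0, 10, length.out = 20)), 0)
  # a single inflated threshold in an otherwise tight group is flagged
  jnds <- c(30, 33, 35, 36, 38, 39, 40, 41, 42, 44, 45, 47, 49, 51, 53, 190)
  flagged <- tukey_outliers(jnds)
  expect_equal(as.integer(flagged), 16L)
  # hinge and weighted-average quartile variants agree on the gross case
  expect_equal(as.integer(tukey_outliers(jnds, method = "weighted")), 16L)
})

test_that("Fisher's Z reproduces the published group comparison", {
  fz <- fisher_z(-0.554, 16, -0.346, 15)
  expect_lt(abs(fz$z - -0.66), 0.005)
  expect_equal(fisher_z(0.4, 20, 0.4, 25)$z, 0)
  expect_equal(fisher_z(0.4, 20, 0.4, 25)$p, 1)
  expect_equal(fisher_z(-0.346, 15, -0.554, 16)$z,
               -fisher_z(-0.554, 16, -0.346, 15)$z)
})

test_that("Steiger's Z is zero under the null identity and antisymmetric", {
  expect_equal(steiger_z(0.5, 0.5, 0.3, 30)$z, 0)
  a <- steiger_z(0.6, 0.3, 0.4, 40)$z
  b <- steiger_z(0.3, 0.6, 0.4, 40)$z
  expect_equal(a, -b)
  expect_error(steiger_z(0.9, -0.9, 0.9, 30),
               class = "voxpitch_invalid_correlation_matrix")
})

test_that("Bonferroni thresholds and decisions match the six-test correction", {
  b <- bonferroni(c(0.001, 0.05, 0.0075), m = 6)
  expect_equal(b$threshold, 0.05 / 6)
  expect_equal(b$significant, c(TRUE, FALSE, TRUE))
  expect_equal(b$p_adjusted, c(0.006, 0.3, 0.045))
  expect_equal(bonferroni(0.04, m = 1)$significant, TRUE)
})

test_that("Shapiro-Wilk wrapper calibrates and rejects degenerate input", {
  set.seed(45)
  rej <- mean(replicate(2000, shapiro_wilk(rnorm(50))$p < 0.05))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  power <- mean(replicate(400, shapiro_wilk(rexp(50))$p < 0.05))
  expect_gt(power, 0.9)
  expect_error(shapiro_wilk(rep(2, 10)), class = "voxpitch_invalid_argument")
  expect_error(shapiro_wilk(rnorm(3)), class = "voxpitch_invalid_argument")
})
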