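# The study's statistical battery as pure functions over summary statistics
# or raw vectors: pooled t-tests with Cohen's d, mixed repeated-measures
# ANOVA (multivariate approach, Wilks' Lambda) with partial eta squared,
# normality-gated Pearson/Spearman correlations, Tukey-fence outlier
# screening, Fisher's Z for independent and Steiger's Z for dependent
# correlation comparisons, and Bonferroni correction.

#' Pooled-variance t-test and Cohen's d from summary statistics
#'
#' Classical independent-samples t-test with the pooled standard deviation
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`;
#' `t = (m1 - m2) / (s_p sqrt(1/n1 + 1/n2))` on `n1+n2-2` df, and Cohen's
#' `d = (m1 - m2) / s_p` (with equal n this is the mean difference over
#' `sqrt((s1^2 + s2^2)/2)`). The identity
#' `d = t * sqrt(1/n1 + 1/n2)` links the two.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Object of class `pooled_ttest` with fields `t`, `df`, `p`
#'   (two-tailed), `d`, and the inputs.
#' @examples
#' pooled_t_and_d(81.64, 10.76, 16, 51.45, 32.05, 16)  # t ~ 3.573, d ~ 1.263
#' @export
pooled_t_and_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0,
            is.finite(mean1), is.finite(mean2))
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  diff <- mean1 - mean2
  if (sp == 0) {
    if (diff != 0)
      stop_vox("zero pooled SD with a nonzero mean difference",
               "voxpitch_infinite_statistic")
    t <- 0; d <- 0
  } else {
    t <- diff / (sp * sqrt(1 / n1 + 1 / n2))
    d <- diff / sp
  }
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), d = d,
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2, pooled_sd = sp),
            class = "pooled_ttest")
}

#' @export
print.pooled_ttest <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (two-tailed), Cohen's d = %.3f\n",
              x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in \[0, 1).
#' @examples
#' eta_p2_from_F(11.594, 1, 30)  # 0.279
#' @export
eta_p2_from_F <- function(F, df1, df2) {
  stopifnot(all(F >= 0), all(df1 >= 1), all(df2 >= 1))
  F * df1 / (F * df1 + df2)
}

# Wilks' Lambda and Rao's F for one hypothesis L %*% B = 0 in the
# multivariate linear model Y = X B + E.
wilks_test <- function(E, H, q, p, ve) {
  lambda <- det(E) / det(E + H)
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  m <- ve - (p - q + 1) / 2
  df1 <- p * q
  df2 <- m * s - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  F <- (1 - lam_s) / lam_s * df2 / df1
  list(lambda = lambda, F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE),
       eta_p2 = 1 - lam_s)
}

#' Mixed repeated-measures ANOVA (multivariate approach)
#'
#' Analyses a subjects x within-levels response matrix with one
#' between-subjects factor. The between-subjects effect is the one-way ANOVA
#' on subject means. The within-subject main effect and the group x within
#' interaction use the multivariate approach on the `levels - 1` successive
#' difference scores: Wilks' Lambda with Rao's F (exact for a 2-group
#' design), numerator df `levels - 1` and denominator df
#' `N - groups - levels + 2`. Partial eta squared is `1 - Lambda` for the
#' multivariate effects and `F df1 / (F df1 + df2)` for the between effect.
#' A univariate mode with Greenhouse-Geisser and Huynh-Feldt corrected
#' p-values is available as a secondary method.
#'
#' @param y Numeric matrix or data frame, subjects in rows, within-subject
#'   levels in columns (no missing cells).
#' @param group Between-subjects factor (length `nrow(y)`).
#' @param method `"multivariate"` (default) or `"univariate"`.
#' @return Object of class `mixed_anova`: a data frame with one row per
#'   effect (`group`, `within`, `interaction`) and columns `F`, `df1`, `df2`,
#'   `p`, `eta_p2`, `lambda` (multivariate effects only; also `eps_gg`,
#'   `p_gg`, `eps_hf`, `p_hf` in univariate mode).
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(32 * 6, mean = rep(c(70, 84), each = 16)), 32, 6)
#' mixed_anova(y, rep(c("ASD", "comparison"), each = 16))
#' @export
mixed_anova <- function(y, group, method = c("multivariate", "univariate")) {
  method <- match.arg(method)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  group <- factor(group)
  N <- nrow(y); p_lev <- ncol(y); g <- nlevels(group)
  stopifnot(length(group) == N, p_lev >= 2, g >= 2)
  if (anyNA(y)) stop_vox("missing cells in the response matrix",
                         "voxpitch_invalid_argument")
  if (any(table(group) < 2))
    stop_vox("each group needs at least 2 subjects", "voxpitch_invalid_argument")

  # between-subjects effect on subject means (delegate to base lm/anova)
  sm <- rowMeans(y)
  atab <- stats::anova(stats::lm(sm ~ group))
  F_b <- atab$`F value`[1]
  df1_b <- atab$Df[1]; df2_b <- atab$Df[2]
  between <- data.frame(effect = "group", F = F_b, df1 = df1_b, df2 = df2_b,
                        p = atab$`Pr(>F)`[1],
                        eta_p2 = eta_p2_from_F(F_b, df1_b, df2_b),
                        lambda = NA_real_)

  if (method == "multivariate") {
    p <- p_lev - 1
    C <- t(diff(diag(p_lev)))           # successive-difference contrasts
    D <- y %*% C
    X <- stats::model.matrix(~ group,
                             contrasts.arg = list(group = "contr.sum"))
    XtXi <- solve(crossprod(X))
    B <- XtXi %*% crossprod(X, D)
    R <- D - X %*% B
    E <- crossprod(R)
    ve <- N - g
    if (ve < p || abs(det(E)) < .Machine$double.eps^2)
      stop_vox("difference-score covariance is rank deficient",
               "voxpitch_rank_deficient")
    hyp <- function(rows) {
      L <- diag(ncol(X))[rows, , drop = FALSE]
      LB <- L %*% B
      H <- t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
      wilks_test(E, H, q = nrow(L), p = p, ve = ve)
    }
    w <- hyp(1L)                         # grand mean of difference scores
    i <- hyp(2:g)                        # group effect on difference scores
    rows <- rbind(
      between,
      data.frame(effect = "within", F = w$F, df1 = w$df1, df2 = w$df2,
                 p = w$p, eta_p2 = w$eta_p2, lambda = w$lambda),
      data.frame(effect = "interaction", F = i$F, df1 = i$df1, df2 = i$df2,
                 p = i$p, eta_p2 = i$eta_p2, lambda = i$lambda))
  } else {
    rows <- rbind_univariate(y, group, between)
  }
  structure(rows, class = c("mixed_anova", "data.frame"))
}

# Univariate mixed ANOVA with sphericity-corrected p-values.
rbind_univariate <- function(y, group, between) {
  N <- nrow(y); p_lev <- ncol(y); g <- nlevels(group)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  lev_means <- colMeans(y)
  grp_means <- rowsum(y, group) / as.vector(table(group))
  cell <- grp_means[group, , drop = FALSE]
  SS_within <- N * sum((lev_means - grand)^2)
  SS_cells <- sum((cell - grand)^2)
  SS_group <- p_lev * sum((rowMeans(cell) - grand)^2)
  SS_inter <- SS_cells - SS_group - SS_within
  SS_subj <- p_lev * sum((subj_means - grand)^2)
  SS_err_w <- sum((y - grand)^2) - SS_cells - (SS_subj - SS_group)
  df_w <- p_lev - 1
  df_i <- (p_lev - 1) * (g - 1)
  df_e <- (N - g) * (p_lev - 1)
  MS_w <- SS_within / df_w; MS_i <- SS_inter / df_i; MS_e <- SS_err_w / df_e
  F_w <- MS_w / MS_e; F_i <- MS_i / MS_e
  # Greenhouse-Geisser / Huynh-Feldt epsilon from the pooled within-group
  # covariance of the responses
  resid <- y - cell
  S <- crossprod(resid) / (N - g)
  k <- p_lev
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  eps_gg <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps_hf <- min(1, (N * (k - 1) * eps_gg - 2) /
                  ((k - 1) * (N - g - (k - 1) * eps_gg)))
  pcor <- function(F, df1, df2, eps)
    stats::pf(F, df1 * eps, df2 * eps, lower.tail = FALSE)
  rbind(
    cbind(between, eps_gg = NA_real_, p_gg = NA_real_,
          eps_hf = NA_real_, p_hf = NA_real_),
    data.frame(effect = "within", F = F_w, df1 = df_w, df2 = df_e,
               p = stats::pf(F_w, df_w, df_e, lower.tail = FALSE),
               eta_p2 = eta_p2_from_F(F_w, df_w, df_e), lambda = NA_real_,
               eps_gg = eps_gg, p_gg = pcor(F_w, df_w, df_e, eps_gg),
               eps_hf = eps_hf, p_hf = pcor(F_w, df_w, df_e, eps_hf)),
    data.frame(effect = "interaction", F = F_i, df1 = df_i, df2 = df_e,
               p = stats::pf(F_i, df_i, df_e, lower.tail = FALSE),
               eta_p2 = eta_p2_from_F(F_i, df_i, df_e), lambda = NA_real_,
               eps_gg = eps_gg, p_gg = pcor(F_i, df_i, df_e, eps_gg),
               eps_hf = eps_hf, p_hf = pcor(F_i, df_i, df_e, eps_hf)))
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 3); df$p <- signif(df$p, 3)
  df$eta_p2 <- round(df$eta_p2, 3)
  if (!is.null(df$lambda)) df$lambda <- round(df$lambda, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Two-tailed (or one-tailed) p-value for a correlation coefficient
#'
#' Uses the t approximation `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` df
#' (applied to Spearman's rho as well, matching common statistical-package
#' output).
#'
#' @param r Correlation coefficient.
#' @param n Sample size.
#' @param tails 1 or 2.
#' @return p-value; for `tails = 1` the probability in the direction of the
#'   observed sign.
#' @examples
#' r_to_p(-0.672, 15)             # ~ .006
#' r_to_p(-0.489, 16, tails = 1)  # ~ .027
#' @export
r_to_p <- function(r, n, tails = 2) {
  stopifnot(abs(r) <= 1, n >= 4, tails %in% c(1, 2))
  if (abs(r) == 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p2 <- 2 * stats::pt(-abs(t), n - 2)
  if (tails == 2) p2 else p2 / 2
}

#' Normality-gated correlation between two variables
#'
#' Pearson's correlation by default; Spearman's rho when `gate = "auto"` and
#' either variable fails the Shapiro-Wilk normality test at alpha = .05.
#' p-values use the t approximation on `n - 2` df; for one-tailed tests the
#' two-tailed p is halved when the observed sign matches the pre-stated
#' direction, and is `1 - p/2` otherwise.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param tails 1 or 2.
#' @param gate `"auto"`, `"pearson"` or `"spearman"`.
#' @param direction Pre-stated sign of the correlation for one-tailed tests:
#'   `"negative"` or `"positive"`.
#' @param spearman_p `"t"` for the t approximation (default) or `"exact"`
#'   for the exact permutation distribution (small n, via
#'   [stats::cor.test()]).
#' @return Object of class `vox_correlation` with `method`, `r`, `n`, `p`,
#'   `tails` and the Shapiro-Wilk gate p-values.
#' @export
correlation <- function(x, y, tails = 2,
                        gate = c("auto", "pearson", "spearman"),
                        direction = c("negative", "positive"),
                        spearman_p = c("t", "exact")) {
  gate <- match.arg(gate)
  direction <- match.arg(direction)
  spearman_p <- match.arg(spearman_p)
  stopifnot(length(x) == length(y), tails %in% c(1, 2))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4)
    stop_vox("need at least 4 complete pairs", "voxpitch_invalid_argument")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_vox("zero variance: correlation undefined",
             "voxpitch_undefined_correlation")
  sw <- c(x = NA_real_, y = NA_real_)
  if (gate == "auto") {
    sw <- c(x = shapiro_wilk(x)$p, y = shapiro_wilk(y)$p)
    method <- if (any(sw < 0.05)) "spearman" else "pearson"
  } else method <- gate
  r <- stats::cor(x, y, method = method)
  if (method == "spearman" && spearman_p == "exact") {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = TRUE))
    p2 <- ct$p.value
  } else {
    p2 <- r_to_p(r, n, tails = 2)
  }
  p <- if (tails == 2) p2 else {
    matches <- (direction == "negative" && r < 0) ||
      (direction == "positive" && r > 0)
    if (matches) p2 / 2 else 1 - p2 / 2
  }
  structure(list(method = method, r = r, n = n, p = p, tails = tails,
                 direction = if (tails == 1) direction else NA_character_,
                 normality_gate = sw, df = n - 2),
            class = "vox_correlation")
}

#' @export
print.vox_correlation <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, n = %d, p = %.4g (%d-tailed)\n",
              if (x$method == "pearson") "Pearson" else "Spearman",
              x$r, x$n, x$p, x$tails))
  if (!anyNA(x$normality_gate))
    cat(sprintf("  Shapiro-Wilk gate: p_x = %.3f, p_y = %.3f\n",
                x$normality_gate[["x"]], x$normality_gate[["y"]]))
  invisible(x)
}

#' Tukey-fence outlier screening
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Quartiles are
#' Tukey's hinges by default (the five-number summary used by boxplots); the
#' weighted-average definition used by some statistical packages is available
#' as an alternative.
#'
#' @param values Numeric vector, n >= 4.
#' @param method `"hinges"` (Tukey, default) or `"weighted"` (quantile
#'   type 6).
#' @param k Fence multiplier (default 1.5).
#' @return Integer indices of flagged values (possibly empty), with the
#'   fences as attribute `fences`.
#' @examples
#' tukey_outliers(c(1:8, 100))  # flags the 9th value
#' @export
tukey_outliers <- function(values, method = c("hinges", "weighted"), k = 1.5) {
  method <- match.arg(method)
  stopifnot(is.numeric(values), sum(is.finite(values)) >= 4)
  q <- if (method == "hinges") stats::fivenum(values)[c(2, 4)]
       else unname(stats::quantile(values, c(0.25, 0.75), type = 6,
                                   na.rm = TRUE))
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  out <- which(values < fences["lower"] | values > fences["upper"])
  attr(out, "fences") <- fences
  out
}

#' Fisher's Z test for two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to the
#' standard normal (two-tailed).
#'
#' @param r1,n1 Correlation and sample size in sample 1.
#' @param r2,n2 Correlation and sample size in sample 2.
#' @return Object of class `corr_comparison` with `z` and `p`.
#' @examples
#' fisher_z(-0.554, 16, -0.346, 15)  # z ~ -0.66
#' @export
fisher_z <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 >= 4, n2 >= 4)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(kind = "independent_fisher", z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 inputs = list(r1 = r1, n1 = n1, r2 = r2, n2 = n2)),
            class = "corr_comparison")
}

#' Steiger's Z test for two dependent correlations sharing one variable
#'
#' Tests `H0: rho12 = rho13` from correlations measured in the same sample,
#' where variable 1 is shared (e.g. emotion recognition correlated with two
#' different perceptual thresholds). Implements the pooled-estimate variant
#' (Steiger 1980): with `rbar = (r12 + r13)/2`,
#' `psi = r23 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r23^2)/2`,
#' `s = psi / (1 - rbar^2)^2`, and
#' `Z = (atanh(r12) - atanh(r13)) sqrt((n - 3) / (2 - 2 s))`.
#'
#' @param r12,r13 The two correlations being compared (shared variable 1).
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size.
#' @return Object of class `corr_comparison` with `z` and `p` (two-tailed).
#' @export
steiger_z <- function(r12, r13, r23, n) {
  stopifnot(n >= 5)
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  if (any(abs(c(r12, r13, r23)) > 1) || min(eigen(R, symmetric = TRUE,
                                                  only.values = TRUE)$values) < -1e-10)
    stop_vox("the correlation triple is not positive semidefinite",
             "voxpitch_invalid_correlation_matrix")
  if (abs(r12) >= 1 || abs(r13) >= 1)
    stop_vox("compared correlations must be strictly inside (-1, 1)",
             "voxpitch_invalid_argument")
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - rbar^2 * (1 - 2 * rbar^2 - r23^2) / 2
  s <- psi / (1 - rbar^2)^2
  z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 - 2 * s))
  structure(list(kind = "dependent_steiger", z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 inputs = list(r12 = r12, r13 = r13, r23 = r23, n = n)),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  lab <- if (x$kind == "independent_fisher") "Fisher's Z (independent samples)"
         else "Steiger's Z (dependent correlations)"
  cat(sprintf("%s: Z = %.3f, p = %.4g\n", lab, x$z, x$p))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p_values Vector of p-values.
#' @param m Number of tests (default `length(p_values)`).
#' @param alpha Family-wise error rate (default .05).
#' @return List with the per-test `threshold` (`alpha/m`), logical
#'   `significant`, and `p_adjusted` (`min(1, p * m)`).
#' @examples
#' bonferroni(c(0.001, 0.05), m = 6)$significant  # TRUE FALSE
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1, all(p_values >= 0 & p_values <= 1))
  list(threshold = alpha / m,
       significant = p_values < alpha / m,
       p_adjusted = pmin(1, p_values * m))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] (Royston's approximation)
#' with the sample-size limits used by the correlation gate.
#'
#' @param values Numeric vector, 4 <= n <= 2000, not constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4 || n > 2000)
    stop_vox("Shapiro-Wilk requires 4 <= n <= 2000", "voxpitch_invalid_argument")
  if (stats::sd(values) == 0)
    stop_vox("constant vector: normality test undefined",
             "voxpitch_invalid_argument")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}
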