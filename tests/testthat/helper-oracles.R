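# Independent oracles used across the suite.

# Repeated-measures effects via stats::anova.mlm on successive difference
# scores (sum-to-zero group coding so the intercept row is the unweighted
# grand mean, as in the package's multivariate approach).
oracle_mlm <- function(y, group) {
  y <- as.matrix(y)
  D <- y %*% t(diff(diag(ncol(y))))
  g <- factor(group)
  n <- nrow(D)
  if (ncol(D) == 1) {
    # two within levels: the multivariate test degenerates to univariate
    # F-tests on the single difference score
    fit <- stats::lm(D[, 1] ~ g, contrasts = list(g = "contr.sum"))
    sm <- stats::summary.lm(fit)$coefficients
    F_w <- sm["(Intercept)", "t value"]^2
    F_i <- stats::anova(fit)$`F value`[1]
    df2 <- n - nlevels(g)
    lam <- function(F) df2 / (df2 + F)
    return(list(within = list(lambda = lam(F_w), F = F_w, df1 = 1, df2 = df2),
                interaction = list(lambda = lam(F_i), F = F_i,
                                   df1 = 1, df2 = df2)))
  }
  fit <- stats::lm(D ~ g, contrasts = list(g = "contr.sum"))
  tab <- stats::anova(fit, test = "Wilks")
  list(within = list(lambda = tab$Wilks[1], F = tab[["approx F"]][1],
                     df1 = tab[["num Df"]][1], df2 = tab[["den Df"]][1]),
       interaction = list(lambda = tab$Wilks[2], F = tab[["approx F"]][2],
                          df1 = tab[["num Df"]][2], df2 = tab[["den Df"]][2]))
}

# Brute-force reversal scan over a trial log: re-derive reversal indices from
# the correctness sequence alone and average the deltas of the trials at
# which the track turned (index - 1) over the final k reversals.
oracle_jnd <- function(trials, terminal_reversals = 10) {
  correct <- trials$correct
  rev_idx <- which(correct[-1] != correct[-length(correct)]) + 1L
  last <- rev_idx[(length(rev_idx) - terminal_reversals + 1):length(rev_idx)]
  mean(trials$delta[last - 1L])
}

# Canonical perfectly-scored 120-trial session.
perfect_session <- function() {
  design <- expand.grid(rep = 1:10, speaker = c("female", "male"),
                        true_emotion = EMOTIONS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(trial_id = seq_len(nrow(design)), speaker = design$speaker,
             true_emotion = design$true_emotion,
             response_emotion = design$true_emotion)
}
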