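# Synthetic matched-pair cohort generator. Emulates the study design: 16
# ASD / comparison pairs matched on gender, age (<= 3 years within pair),
# handedness and full-scale IQ (<= 15 points within pair), with per-group
# marginal moments and within-group correlation structure taken from the
# published summary tables. Construction is copula-style: a one-factor latent
# standard-normal structure (a shared "ability" factor carries the target
# correlations, guaranteeing a positive-semidefinite latent covariance) with
# moment-matched marginal transforms (scaled logit for percentage scales,
# lognormal for thresholds and symptom scores). First-order Hermite
# attenuation of each transform is compensated analytically so observed
# moments and correlations land on the targets.

# ---- moment-matched marginal transforms -----------------------------------

# quadrature grid for E[f(Z)], Z ~ N(0,1)
.z_grid <- seq(-8, 8, by = 0.02)
.z_w <- stats::dnorm(.z_grid) * 0.02

norm_e <- function(f) sum(f(.z_grid) * .z_w)

# transform object: g(z) observed value; c1 = Cov(Z, g(Z)) (first Hermite
# coefficient, used for attenuation compensation); m, s observed moments.
make_lognormal_transform <- function(m, s) {
  stopifnot(m > 0, s >= 0)
  if (s == 0) return(make_const_transform(m))
  sigma2 <- log(1 + s^2 / m^2)
  mu <- log(m) - sigma2 / 2
  sigma <- sqrt(sigma2)
  g <- function(z) exp(mu + sigma * z)
  list(g = g, m = m, s = s, c1 = m * sigma)  # Cov(Z, e^(mu + sigma Z))
}

make_const_transform <- function(m) {
  list(g = function(z) rep(m, length(z)), m = m, s = 0, c1 = 0)
}

# value = upper * plogis(a + b z), with (a, b) solved so that the observed
# mean and SD equal (m, s). Nested root-finding: for each candidate b the
# intercept a is solved for the mean, then b is solved for the SD.
make_logit_transform <- function(m, s, upper = 100) {
  stopifnot(m > 0, m < upper, s >= 0)
  if (s == 0) return(make_const_transform(m))
  mean_of <- function(a, b) norm_e(function(z) upper * stats::plogis(a + b * z))
  solve_a <- function(b)
    stats::uniroot(function(a) mean_of(a, b) - m, c(-30, 30), tol = 1e-12)$root
  sd_of <- function(b) {
    a <- solve_a(b)
    v <- norm_e(function(z) (upper * stats::plogis(a + b * z) - m)^2)
    sqrt(v)
  }
  b_hi <- 20
  if (sd_of(b_hi) < s)
    stop_vox(sprintf("SD %.3g not achievable for a mean of %.3g on [0, %g]",
                     s, m, upper), "voxpitch_invalid_argument")
  b <- stats::uniroot(function(b) sd_of(b) - s, c(1e-4, b_hi), tol = 1e-10)$root
  a <- solve_a(b)
  g <- function(z) upper * stats::plogis(a + b * z)
  c1 <- norm_e(function(z) z * g(z))
  list(g = g, m = m, s = s, c1 = c1, a = a, b = b)
}

# ---- cohort specification --------------------------------------------------

#' Specify a synthetic matched-pair cohort
#'
#' Defaults reproduce the published group summaries: per-emotion and total
#' recognition accuracy, vocal pitch JND (cents), vocal timbre JND (SER-%),
#' non-vocal pitch accuracy, AQ, ADOS communication score (ASD only), plus
#' the within-group correlation targets between emotion recognition and the
#' other measures. Matching tolerances are age <= 3 years and full-scale IQ
#' <= 15 points within each pair.
#'
#' @param n_pairs Number of matched pairs (default 16).
#' @param correlations Named list per group of correlation targets between
#'   the emotion total and other measures; see the default for the shape.
#'   The emotion-timbre and emotion-non-vocal targets default to 0 (the study
#'   reports them as non-significant without printing values).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 16, correlations = NULL) {
  stopifnot(n_pairs >= 2)
  ps <- printed_summaries()
  emo <- ps$emotion[ps$emotion$measure != "total", ]
  total <- ps$emotion[ps$emotion$measure == "total", ]
  spec <- list(
    n_pairs = as.integer(n_pairs),
    emotions = EMOTIONS,
    emotion_means = list(asd = stats::setNames(emo$m_asd, emo$measure),
                         comparison = stats::setNames(emo$m_comp, emo$measure)),
    emotion_sds = list(asd = stats::setNames(emo$sd_asd, emo$measure),
                       comparison = stats::setNames(emo$sd_comp, emo$measure)),
    emotion_total = list(asd = c(m = total$m_asd, s = total$sd_asd),
                         comparison = c(m = total$m_comp, s = total$sd_comp)),
    pitch_jnd = list(asd = c(m = 65.18, s = 47.69),
                     comparison = c(m = 36.02, s = 21.39)),
    timbre_jnd = list(asd = c(m = 4.28, s = 2.17),
                      comparison = c(m = 3.45, s = 1.62)),
    nonvocal_pitch = list(asd = c(m = 82.27, s = 8.03),
                          comparison = c(m = 85.56, s = 7.57)),
    aq = list(asd = c(m = 39.81, s = 6.61),
              comparison = c(m = 14.13, s = 4.77)),
    ados_comm = c(m = 3.80, s = 1.27),
    age = list(asd = c(m = 33.75, s = 10.12),
               comparison = c(m = 33.69, s = 9.58)),
    iq_full = list(asd = c(m = 110.31, s = 13.79),
                   comparison = c(m = 111.50, s = 10.97)),
    iq_verbal = list(asd = c(m = 110.75, s = 12.35),
                     comparison = c(m = 108.75, s = 12.59)),
    iq_performance = list(asd = c(m = 107.38, s = 17.55),
                          comparison = c(m = 112.69, s = 9.59)),
    n_female_pairs = 3L, n_left_pairs = 2L,
    aq_cutoff = 32,
    match_age_years = 3, match_iq_points = 15,
    correlations = correlations %||% list(
      asd = c(pitch_jnd = -0.346, timbre_jnd = 0, nonvocal_pitch = 0,
              aq = -0.197, ados_comm = -0.672),
      comparison = c(pitch_jnd = -0.554, timbre_jnd = 0, nonvocal_pitch = 0,
                     aq = -0.501, ados_comm = NA))
  )
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d matched pairs per group\n", x$n_pairs))
  cat(sprintf("  emotion total: ASD %.2f (%.2f), comparison %.2f (%.2f)\n",
              x$emotion_total$asd["m"], x$emotion_total$asd["s"],
              x$emotion_total$comparison["m"], x$emotion_total$comparison["s"]))
  cat(sprintf("  pitch JND: ASD %.2f (%.2f), comparison %.2f (%.2f) cents\n",
              x$pitch_jnd$asd["m"], x$pitch_jnd$asd["s"],
              x$pitch_jnd$comparison["m"], x$pitch_jnd$comparison["s"]))
  cat("  correlation targets (emotion total vs measure):\n")
  for (g in names(x$correlations)) {
    tg <- x$correlations[[g]]
    cat(sprintf("    %s: %s\n", g,
                paste(sprintf("%s=%.3f", names(tg), tg), collapse = ", ")))
  }
  invisible(x)
}

# Per-group generation machinery: solve the factor loadings once per spec.
group_generator <- function(spec, grp) {
  emo_m <- spec$emotion_means[[grp]]
  emo_s <- spec$emotion_sds[[grp]]
  tr_emo <- Map(function(m, s) make_logit_transform(m, s, 100), emo_m, emo_s)
  c1 <- vapply(tr_emo, `[[`, numeric(1), "c1")
  s_tot <- spec$emotion_total[[grp]]["s"]
  # loading of every per-emotion latent on the ability factor, calibrated so
  # that the observed total (mean of the six transformed scores) has the
  # target SD; first-order Hermite term Cov(g_j, g_k) ~ rho^2 c1_j c1_k.
  num <- 36 * s_tot^2 - sum(emo_s^2)
  den <- sum(c1)^2 - sum(c1^2)
  rho2 <- max(0, num / den)
  rho <- sqrt(min(rho2, 0.98^2))
  # correlation of the observed total with the ability factor
  c_tot <- rho * sum(c1) / (6 * s_tot)

  others <- list(
    pitch_jnd = make_lognormal_transform(spec$pitch_jnd[[grp]]["m"],
                                         spec$pitch_jnd[[grp]]["s"]),
    timbre_jnd = make_lognormal_transform(spec$timbre_jnd[[grp]]["m"],
                                          spec$timbre_jnd[[grp]]["s"]),
    nonvocal_pitch = make_logit_transform(spec$nonvocal_pitch[[grp]]["m"],
                                          spec$nonvocal_pitch[[grp]]["s"], 100),
    aq = make_logit_transform(spec$aq[[grp]]["m"], spec$aq[[grp]]["s"], 50))
  if (grp == "asd")
    others$ados_comm <- make_lognormal_transform(spec$ados_comm["m"],
                                                 spec$ados_comm["s"])
  targets <- spec$correlations[[grp]]
  loadings <- vapply(names(others), function(v) {
    r_target <- if (v %in% names(targets)) targets[[v]] else 0
    if (is.na(r_target) || r_target == 0) return(0)
    kappa <- others[[v]]$c1 / others[[v]]$s   # transform attenuation
    lam <- r_target / (c_tot * kappa)
    if (!is.finite(lam)) 0 else max(-0.98, min(0.98, lam))
  }, numeric(1))
  list(tr_emo = tr_emo, rho = rho, c_tot = c_tot,
       others = others, loadings = loadings)
}

#' Generate a synthetic matched-pair cohort
#'
#' Draws `n_pairs` ASD / comparison participant pairs with the marginal
#' moments and within-group correlation structure of the [cohort_spec()].
#' Pairs are matched on gender, handedness, age and full-scale IQ by sharing
#' a latent pair deviate, so the matching tolerances hold by construction.
#' Comparison-group AQ is screened below the clinical cutoff (32), mirroring
#' the study's inclusion criterion.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; identical seeds give identical cohorts.
#' @return Data frame of class `vox_cohort`, one row per participant:
#'   `id`, `group` (`"asd"`/`"comparison"`), `pair_id`, `age`, `gender`,
#'   `handedness`, `iq_full`, `iq_verbal`, `iq_performance`, `aq`,
#'   `ados_comm` (NA for comparison), `emotion_total`,
#'   `emotion_<category>` (six columns), `pitch_jnd`, `timbre_jnd`,
#'   `nonvocal_pitch_pct`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 11)
#' aggregate(emotion_total ~ group, cohort, mean)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_pairs
    gens <- list(asd = group_generator(spec, "asd"),
                 comparison = group_generator(spec, "comparison"))

    female_pairs <- sample(n, min(spec$n_female_pairs, n))
    left_pairs <- sample(n, min(spec$n_left_pairs, n))
    z_age <- pmax(-3.5, pmin(3.5, stats::rnorm(n)))
    z_iqf <- pmax(-3.5, pmin(3.5, stats::rnorm(n)))
    z_iqv <- stats::rnorm(n); z_iqp <- stats::rnorm(n)

    one_group <- function(grp) {
      gen <- gens[[grp]]
      a <- stats::rnorm(n)   # latent ability factor
      emo <- sapply(seq_along(gen$tr_emo), function(j) {
        zj <- gen$rho * a + sqrt(1 - gen$rho^2) * stats::rnorm(n)
        gen$tr_emo[[j]]$g(zj)
      })
      colnames(emo) <- names(gen$tr_emo)
      vars <- sapply(names(gen$others), function(v) {
        lam <- gen$loadings[[v]]
        zv <- lam * a + sqrt(1 - lam^2) * stats::rnorm(n)
        gen$others[[v]]$g(zv)
      })
      age <- spec$age[[grp]]["m"] + spec$age[[grp]]["s"] * z_age +
        (if (grp == "asd") stats::runif(n, -1, 1) else 0)
      iqf <- spec$iq_full[[grp]]["m"] + spec$iq_full[[grp]]["s"] * z_iqf +
        (if (grp == "asd") stats::runif(n, -1, 1) else 0)
      iqv <- spec$iq_verbal[[grp]]["m"] + spec$iq_verbal[[grp]]["s"] * z_iqv
      iqp <- spec$iq_performance[[grp]]["m"] + spec$iq_performance[[grp]]["s"] * z_iqp
      aq <- vars[, "aq"]
      if (grp == "comparison") aq <- pmin(aq, spec$aq_cutoff - 0.5)
      data.frame(
        id = sprintf("%s_%02d", grp, seq_len(n)),
        group = grp, pair_id = seq_len(n),
        age = age,
        gender = ifelse(seq_len(n) %in% female_pairs, "female", "male"),
        handedness = ifelse(seq_len(n) %in% left_pairs, "left", "right"),
        iq_full = iqf, iq_verbal = iqv, iq_performance = iqp,
        aq = aq,
        ados_comm = if (grp == "asd") vars[, "ados_comm"] else NA_real_,
        emotion_total = rowMeans(emo),
        emotion_happiness = emo[, "happiness"],
        emotion_sadness = emo[, "sadness"],
        emotion_fear = emo[, "fear"],
        emotion_anger = emo[, "anger"],
        emotion_disgust = emo[, "disgust"],
        emotion_neutral = emo[, "neutral"],
        pitch_jnd = vars[, "pitch_jnd"],
        timbre_jnd = vars[, "timbre_jnd"],
        nonvocal_pitch_pct = vars[, "nonvocal_pitch"])
    }
    out <- rbind(one_group("asd"), one_group("comparison"))
    rownames(out) <- NULL
    class(out) <- c("vox_cohort", "data.frame")
    out
  })
}

#' @export
print.vox_cohort <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Synthetic cohort: %d participants (%d pairs)\n",
              nrow(df), nrow(df) / 2))
  agg <- stats::aggregate(
    df[, c("emotion_total", "pitch_jnd", "timbre_jnd", "aq")],
    by = list(group = df$group), FUN = function(v) round(mean(v), 2))
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Generate a 6-AFC emotion-recognition session for one participant
#'
#' Builds the canonical 120-trial session (20 per emotion, 10 per speaker)
#' and draws responses: each trial is correct with the participant's
#' per-emotion accuracy (as a probability); errors are distributed over the
#' other five emotions by the confusion kernel (uniform by default).
#'
#' @param profile Named vector of per-emotion accuracies in percent
#'   (names = [EMOTIONS]).
#' @param seed Optional seed.
#' @param confusion_kernel Optional 6 x 6 matrix of error weights (rows =
#'   presented emotion; the diagonal is ignored); default uniform.
#' @param stimulus_attributes Optional data frame of 120 rows with
#'   per-stimulus covariates (`intensity_score`, `freq_range`), e.g. from
#'   [generate_stimulus_attributes()]; joined onto the trial table.
#' @param intensity_effect Log-odds shift in trial-level accuracy per
#'   within-emotion standard deviation of the intensity score (default 0, in
#'   which case the session recovers the profile in expectation exactly;
#'   nonzero values preserve the per-emotion means up to a small
#'   logistic-averaging term).
#' @return Trial data frame: `trial_id`, `speaker`, `true_emotion`,
#'   `response_emotion`, plus covariate columns.
#' @export
generate_emotion_session <- function(profile, seed = NULL,
                                     confusion_kernel = NULL,
                                     stimulus_attributes = NULL,
                                     intensity_effect = 0) {
  stopifnot(all(EMOTIONS %in% names(profile)),
            all(profile >= 0 & profile <= 100))
  with_seed(seed, {
    design <- expand.grid(rep = 1:10, speaker = c("female", "male"),
                          true_emotion = EMOTIONS,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(design)
    trials <- data.frame(trial_id = seq_len(n),
                         speaker = design$speaker,
                         true_emotion = design$true_emotion)
    if (!is.null(stimulus_attributes)) {
      stopifnot(nrow(stimulus_attributes) == n)
      trials <- cbind(trials, stimulus_attributes[
        , setdiff(names(stimulus_attributes), names(trials)), drop = FALSE])
    }
    trials <- trials[sample(n), ]       # randomised presentation order
    trials$trial_id <- seq_len(n)
    rownames(trials) <- NULL
    p <- profile[trials$true_emotion] / 100
    if (intensity_effect != 0) {
      if (is.null(trials$intensity_score))
        stop_vox("intensity_effect needs an intensity_score column",
                 "voxpitch_invalid_argument")
      # centre and scale within emotion so the per-emotion accuracy profile
      # is preserved in expectation while harder stimuli within an emotion
      # are recognised less often
      zint <- stats::ave(trials$intensity_score, trials$true_emotion,
                         FUN = function(v) {
                           s <- stats::sd(v)
                           if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
                         })
      p <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) +
                           intensity_effect * zint)
    }
    correct <- stats::runif(n) < p
    resp <- trials$true_emotion
    wrong <- which(!correct)
    for (i in wrong) {
      alt <- setdiff(EMOTIONS, trials$true_emotion[i])
      w <- if (is.null(confusion_kernel)) rep(1, 5) else {
        ck <- confusion_kernel[trials$true_emotion[i], alt]
        if (all(ck == 0)) rep(1, 5) else ck
      }
      resp[i] <- sample(alt, 1, prob = w)
    }
    trials$response_emotion <- resp
    trials
  })
}

#' Synthetic per-stimulus covariates for the emotion session
#'
#' Emotional intensity (independent-rater recognition accuracy, %) and F0
#' frequency range (Hz) for each of the 120 stimuli: intensity is drawn
#' around emotion-specific anchors (neutral and anger easy, disgust hard),
#' frequency range around emotion-specific spans. These emulate the shape of
#' the stimulus characterisation, not any measured values.
#'
#' @param seed Optional seed.
#' @return Data frame of 120 rows (`rep` x `speaker` x `true_emotion` in the
#'   canonical order) with columns `intensity_score`, `freq_range`.
#' @export
generate_stimulus_attributes <- function(seed = NULL) {
  with_seed(seed, {
    design <- expand.grid(rep = 1:10, speaker = c("female", "male"),
                          true_emotion = EMOTIONS,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    anchors <- c(happiness = 80, sadness = 78, fear = 82, anger = 90,
                 disgust = 62, neutral = 92)
    spans <- c(happiness = 160, sadness = 70, fear = 180, anger = 150,
               disgust = 90, neutral = 50)
    data.frame(
      intensity_score = pmin(100, pmax(
        0, anchors[design$true_emotion] + stats::rnorm(nrow(design), 0, 8))),
      freq_range = pmax(10, spans[design$true_emotion] *
                          exp(stats::rnorm(nrow(design), 0, 0.25))))
  })
}

#' Observers whose 75%-correct point equals each participant's JND
#'
#' Builds one sigmoid observer per cohort row so the staircase -> JND ->
#' statistics pipeline round-trips: `threshold_at(obs, 0.75)` equals the
#' participant's generated threshold on the requested scale.
#'
#' @param cohort A [generate_cohort()] table (or any data frame with the JND
#'   column).
#' @param scale `"pitch"` (column `pitch_jnd`) or `"timbre"`
#'   (`timbre_jnd`).
#' @param slope,lapse Observer shape parameters shared across participants.
#' @return Named list of [observer()] objects (names = participant ids).
#' @export
generate_staircase_observers <- function(cohort, scale = c("pitch", "timbre"),
                                         slope = 8, lapse = 0.02) {
  scale <- match.arg(scale)
  col <- if (scale == "pitch") "pitch_jnd" else "timbre_jnd"
  jnds <- cohort[[col]]
  stopifnot(!is.null(jnds), all(jnds > 0))
  psi75 <- (0.75 - 0.5) / (0.5 - lapse / 2)
  adj <- exp(stats::qlogis(psi75) / slope)
  obs <- lapply(jnds, function(j)
    sigmoid_observer(threshold = j / adj, slope = slope, lapse = lapse))
  names(obs) <- if (!is.null(cohort$id)) cohort$id else seq_along(jnds)
  obs
}
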