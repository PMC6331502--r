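# Scoring of the six-alternative forced-choice vocal emotion recognition test:
# design validation (120 trials, 20 per emotion, 10 per emotion x speaker),
# per-emotion accuracy and confusion matrices, and quartile binning of
# stimulus-level covariates (emotional intensity, F0 frequency range) for the
# 4-level mixed ANOVA.

#' Validate the design of an emotion-recognition session
#'
#' The canonical session has 120 trials: each of the six emotions presented
#' 20 times, 10 spoken by the female and 10 by the male speaker.
#'
#' @param trials Data frame with columns `true_emotion`, `speaker`, and
#'   optionally `response_emotion` and `trial_id`.
#' @return A list with `valid` (logical) and `violations` (character vector),
#'   plus the observed counts, of class `emotion_design_report`.
#' @export
validate_design <- function(trials) {
  trials <- as.data.frame(trials)
  violations <- character(0)
  if (!all(c("true_emotion", "speaker") %in% names(trials)))
    stop_vox("trials must have columns true_emotion and speaker",
             "voxpitch_invalid_argument")
  bad_emo <- setdiff(unique(as.character(trials$true_emotion)), EMOTIONS)
  if (length(bad_emo))
    violations <- c(violations, sprintf("unknown emotion categories: %s",
                                        paste(bad_emo, collapse = ", ")))
  if ("response_emotion" %in% names(trials)) {
    bad_resp <- setdiff(unique(as.character(trials$response_emotion)), EMOTIONS)
    if (length(bad_resp))
      violations <- c(violations, sprintf("responses outside the 6 categories: %s",
                                          paste(bad_resp, collapse = ", ")))
  }
  if (nrow(trials) != 120)
    violations <- c(violations, sprintf("expected 120 trials, found %d",
                                        nrow(trials)))
  emo_counts <- table(factor(trials$true_emotion, levels = EMOTIONS))
  if (any(emo_counts != 20))
    violations <- c(violations, sprintf(
      "emotions not presented 20 times each (%s)",
      paste(sprintf("%s=%d", names(emo_counts), emo_counts), collapse = ", ")))
  cell_counts <- table(factor(trials$true_emotion, levels = EMOTIONS),
                       factor(trials$speaker, levels = c("female", "male")))
  if (any(cell_counts != 10))
    violations <- c(violations,
                    "emotion x speaker cells not balanced at 10 trials each")
  structure(list(valid = length(violations) == 0, violations = violations,
                 emotion_counts = emo_counts, cell_counts = cell_counts),
            class = "emotion_design_report")
}

#' @export
print.emotion_design_report <- function(x, ...) {
  if (x$valid) {
    cat("Session design valid: 120 trials, 20 per emotion, 10 per emotion x speaker\n")
  } else {
    cat("Session design violations:\n")
    for (v in x$violations) cat(" -", v, "\n")
  }
  invisible(x)
}

#' Score a six-alternative emotion-recognition session
#'
#' @param trials Data frame with columns `true_emotion` and
#'   `response_emotion` (both within the six categories).
#' @param check_design Validate the canonical 120-trial design first
#'   (default TRUE); set FALSE to score arbitrary trial tables.
#' @return Object of class `emotion_score`: `per_emotion_accuracy` (named %,
#'   diagonal of the confusion matrix), `total_accuracy` (% correct pooled
#'   over all trials) and `confusion` (6 x 6 matrix of row percentages, rows
#'   = presented emotion, columns = response).
#' @examples
#' s <- generate_emotion_session(stats::setNames(rep(100, 6), EMOTIONS), seed = 1)
#' score_session(s)$total_accuracy
#' @export
score_session <- function(trials, check_design = TRUE) {
  trials <- as.data.frame(trials)
  if (check_design) {
    report <- validate_design(trials)
    if (!report$valid)
      stop_vox(paste0("invalid session design: ",
                      paste(report$violations, collapse = "; "),
                      " (use check_design = FALSE to override)"),
               "voxpitch_invalid_design")
  }
  truth <- factor(trials$true_emotion, levels = EMOTIONS)
  resp <- factor(trials$response_emotion, levels = EMOTIONS)
  counts <- table(truth, resp)
  row_n <- rowSums(counts)
  if (any(row_n == 0))
    stop_vox("cannot score: some emotion has no trials", "voxpitch_invalid_design")
  confusion <- sweep(counts, 1, row_n, "/") * 100
  per_emotion <- diag(as.matrix(confusion))
  names(per_emotion) <- EMOTIONS
  total <- 100 * sum(diag(as.matrix(counts))) / sum(counts)
  structure(list(per_emotion_accuracy = per_emotion, total_accuracy = total,
                 confusion = as.matrix(confusion), n_trials = sum(counts)),
            class = "emotion_score")
}

#' @export
print.emotion_score <- function(x, digits = 1, ...) {
  cat(sprintf("Emotion recognition score (%d trials): total %.*f%% correct\n",
              x$n_trials, digits, x$total_accuracy))
  print(round(x$per_emotion_accuracy, digits))
  invisible(x)
}

#' Bin stimuli into four levels of a stimulus covariate
#'
#' Partitions the trials into four equal-sized levels ("very low", "low",
#' "high", "very high") by the quartiles of a per-stimulus variable
#' (emotional intensity or F0 frequency range). Ties straddling a quartile
#' boundary are resolved by stable trial-id order, so the split is always as
#' equal as the trial count allows.
#'
#' @param trials Trial data frame containing the variable column and
#'   (optionally) `trial_id` for stable tie-breaking.
#' @param variable `"intensity"` (column `intensity_score`) or
#'   `"freq_range"` (column `freq_range`).
#' @param n_levels Number of levels (default 4).
#' @return Ordered factor of level assignments, one per trial.
#' @export
bin_levels <- function(trials, variable = c("intensity", "freq_range"),
                       n_levels = 4) {
  variable <- match.arg(variable)
  trials <- as.data.frame(trials)
  col <- if (variable == "intensity") "intensity_score" else "freq_range"
  if (!col %in% names(trials))
    stop_vox(sprintf("column '%s' missing from trials", col),
             "voxpitch_invalid_argument")
  values <- trials[[col]]
  if (anyNA(values))
    stop_vox(sprintf("column '%s' has missing values", col),
             "voxpitch_invalid_argument")
  if (diff(range(values)) == 0)
    stop_vox("all stimulus values are equal; levels are undefined",
             "voxpitch_degenerate_binning")
  ids <- if ("trial_id" %in% names(trials)) trials$trial_id else seq_len(nrow(trials))
  ord <- order(values, ids)
  n <- length(values)
  sizes <- rep(n %/% n_levels, n_levels)
  extra <- n %% n_levels
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lev_labels <- if (n_levels == 4) c("very low", "low", "high", "very high")
                else paste("level", seq_len(n_levels))
  assignment <- integer(n)
  assignment[ord] <- rep(seq_len(n_levels), times = sizes)
  factor(lev_labels[assignment], levels = lev_labels, ordered = TRUE)
}

#' Mean accuracy per covariate level for one session
#'
#' @param trials Trial data frame with `true_emotion` and `response_emotion`.
#' @param levels Level assignment from [bin_levels()] (same length).
#' @return Named numeric vector of percent correct per level.
#' @export
level_accuracy <- function(trials, levels) {
  trials <- as.data.frame(trials)
  stopifnot(length(levels) == nrow(trials))
  correct <- as.character(trials$true_emotion) ==
    as.character(trials$response_emotion)
  100 * vapply(split(correct, levels), mean, numeric(1))
}

#' Mixed ANOVA over covariate levels
#'
#' Convenience wrapper delegating to [mixed_anova()]: the within-subject
#' factor is the 4-level stimulus covariate, the between-subject factor the
#' group label.
#'
#' @param level_means Participants x levels matrix of mean accuracies.
#' @param group Group label per participant.
#' @param ... Passed to [mixed_anova()].
#' @return See [mixed_anova()].
#' @export
level_anova <- function(level_means, group, ...) {
  mixed_anova(level_means, group, ...)
}
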