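# Weighted one-up/one-down adaptive staircase with phase-switching step sizes
# and the reversal-mean JND estimator. The procedure is generic over the
# stimulus-difference scale: the pitch test runs on musical cents, the timbre
# test on SER percent. With up step S_up after an incorrect response and down
# step S_down after a correct one, the track converges to the stimulus
# difference where P(correct) = S_up / (S_up + S_down); both built-in
# configurations target 0.75.

#' Configure a weighted up-down staircase
#'
#' The track starts at `initial_delta`; the difference increases by the up
#' step after each incorrect response and decreases by the down step after
#' each correct response. After `phase_switch_reversals` reversals the
#' phase-2 (finer) step sizes take over, and the run terminates after a
#' further `terminal_reversals` reversals. The JND is the arithmetic mean of
#' the stimulus differences at those final reversal trials.
#'
#' @param initial_delta Starting stimulus difference.
#' @param up_step_phase1,down_step_phase1 Phase-1 step sizes (up > down).
#' @param up_step_phase2,down_step_phase2 Phase-2 step sizes (up > down).
#' @param phase_switch_reversals Reversals before switching to phase 2
#'   (default 4).
#' @param terminal_reversals Further reversals to termination (default 10).
#' @param delta_floor,delta_ceiling Clamping bounds for the difference.
#' @param max_trials Safety cap; exceeded means the observer never reverses
#'   and an error of class `voxpitch_nonconvergence` is signalled.
#' @return Object of class `staircase_config`.
#' @export
staircase_config <- function(initial_delta,
                             up_step_phase1, down_step_phase1,
                             up_step_phase2, down_step_phase2,
                             phase_switch_reversals = 4,
                             terminal_reversals = 10,
                             delta_floor, delta_ceiling,
                             max_trials = 10000) {
  steps <- c(up_step_phase1, down_step_phase1, up_step_phase2, down_step_phase2)
  stopifnot(all(is.finite(steps)), all(steps > 0),
            up_step_phase1 > down_step_phase1,
            up_step_phase2 > down_step_phase2,
            phase_switch_reversals >= 1, terminal_reversals >= 2,
            delta_floor >= 0, delta_floor < delta_ceiling,
            initial_delta >= delta_floor, initial_delta <= delta_ceiling,
            max_trials >= 1)
  structure(list(initial_delta = initial_delta,
                 up_step_phase1 = up_step_phase1,
                 down_step_phase1 = down_step_phase1,
                 up_step_phase2 = up_step_phase2,
                 down_step_phase2 = down_step_phase2,
                 phase_switch_reversals = phase_switch_reversals,
                 terminal_reversals = terminal_reversals,
                 delta_floor = delta_floor, delta_ceiling = delta_ceiling,
                 max_trials = max_trials),
            class = "staircase_config")
}

#' @rdname staircase_config
#' @details `pitch_staircase_config()` is the vocal pitch test: initial
#'   difference 100 cents, phase-1 steps 30 (up) / 10 (down) cents, phase-2
#'   steps 6 / 2 cents. `timbre_staircase_config()` is the vocal timbre test
#'   on the SER-percent scale: initial 12%, steps 3 / 1 then 0.6 / 0.2.
#'   Floors and ceilings (1--2400 cents; 0.1--30%) are package defaults: the
#'   procedure itself does not define behaviour at the scale boundary, so the
#'   difference is clamped there without disturbing correctness bookkeeping.
#' @export
pitch_staircase_config <- function() {
  staircase_config(initial_delta = 100,
                   up_step_phase1 = 30, down_step_phase1 = 10,
                   up_step_phase2 = 6, down_step_phase2 = 2,
                   delta_floor = 1, delta_ceiling = 2400)
}

#' @rdname staircase_config
#' @export
timbre_staircase_config <- function() {
  staircase_config(initial_delta = 12,
                   up_step_phase1 = 3, down_step_phase1 = 1,
                   up_step_phase2 = 0.6, down_step_phase2 = 0.2,
                   delta_floor = 0.1, delta_ceiling = 30)
}

#' @export
print.staircase_config <- function(x, ...) {
  cat(sprintf(
    "Weighted up-down staircase: start %g, steps %g/%g then %g/%g,\n  switch after %d reversals, stop after %d more; bounds [%g, %g]\n  (converges to the %.0f%%-correct point)\n",
    x$initial_delta, x$up_step_phase1, x$down_step_phase1,
    x$up_step_phase2, x$down_step_phase2,
    x$phase_switch_reversals, x$terminal_reversals,
    x$delta_floor, x$delta_ceiling,
    100 * x$up_step_phase1 / (x$up_step_phase1 + x$down_step_phase1)))
  invisible(x)
}

#' Detect reversals in a correctness sequence
#'
#' Trial `i >= 2` is a reversal iff its correctness differs from trial
#' `i - 1`'s; the first trial is never a reversal.
#'
#' @param correct_sequence Logical vector of per-trial correctness.
#' @return Integer vector of reversal trial indices (possibly empty).
#' @examples
#' detect_reversals(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))  # 3 4 5 7
#' @export
detect_reversals <- function(correct_sequence) {
  stopifnot(is.logical(correct_sequence), length(correct_sequence) >= 1,
            !anyNA(correct_sequence))
  which(diff(correct_sequence) != 0) + 1L
}

#' Next stimulus difference after a response
#'
#' @param current Current stimulus difference.
#' @param correct Was the response correct?
#' @param phase Staircase phase, 1 or 2.
#' @param config A [staircase_config()].
#' @return The updated difference, clamped to the configured bounds.
#' @export
next_delta <- function(current, correct, phase, config) {
  stopifnot(inherits(config, "staircase_config"), phase %in% c(1, 2),
            is.logical(correct), length(correct) == 1L)
  step <- if (phase == 1) {
    if (correct) -config$down_step_phase1 else config$up_step_phase1
  } else {
    if (correct) -config$down_step_phase2 else config$up_step_phase2
  }
  min(max(current + step, config$delta_floor), config$delta_ceiling)
}

#' Run one adaptive staircase against a simulated observer
#'
#' Presents two intervals per trial (the manipulated stimulus placed at
#' random), queries the observer, applies the weighted up-down rule, switches
#' to phase-2 step sizes once `phase_switch_reversals` reversals have been
#' registered, and terminates after a further `terminal_reversals` reversals.
#' The JND estimate is the mean of the stimulus differences attributed to
#' those final reversals (the delta at which the track turned; see
#' [estimate_jnd()]).
#'
#' @param obs A [observer()] defined on the config's difference scale.
#' @param config A [staircase_config()].
#' @param seed Optional integer; identical seeds give identical runs.
#' @return Object of class `staircase_run`: a list with `trials` (data frame
#'   with columns `index`, `delta`, `order`, `response`, `correct`,
#'   `is_reversal`, `phase`), `reversal_deltas` (final reversal values) and
#'   `jnd`.
#' @examples
#' run <- run_staircase(sigmoid_observer(40, slope = 8), pitch_staircase_config(),
#'                      seed = 1)
#' run$jnd
#' @export
run_staircase <- function(obs, config, seed = NULL) {
  stopifnot(inherits(obs, "vox_observer"), inherits(config, "staircase_config"))
  with_seed(seed, {
    total_rev <- config$phase_switch_reversals + config$terminal_reversals
    nmax <- config$max_trials
    delta <- numeric(nmax); ord <- integer(nmax); resp <- integer(nmax)
    corr <- logical(nmax); isrev <- logical(nmax); phs <- integer(nmax)
    d <- config$initial_delta
    phase <- 1L
    n_rev <- 0L
    i <- 0L
    prev_correct <- NA
    while (n_rev < total_rev) {
      i <- i + 1L
      if (i > nmax)
        stop_vox(sprintf(
          "staircase did not accumulate %d reversals within %d trials",
          total_rev, nmax), "voxpitch_nonconvergence")
      manipulated <- sample(2L, 1L)
      response <- respond(obs, d, manipulated)
      if (!response %in% c(1L, 2L))
        stop_vox("observer returned an invalid response",
                 "voxpitch_invalid_observer")
      correct <- response == manipulated
      reversal <- !is.na(prev_correct) && correct != prev_correct
      delta[i] <- d; ord[i] <- manipulated; resp[i] <- response
      corr[i] <- correct; isrev[i] <- reversal; phs[i] <- phase
      if (reversal) n_rev <- n_rev + 1L
      if (n_rev >= config$phase_switch_reversals) phase <- 2L
      d <- next_delta(d, correct, phase, config)
      prev_correct <- correct
    }
    trials <- data.frame(index = seq_len(i), delta = delta[seq_len(i)],
                         order = ord[seq_len(i)], response = resp[seq_len(i)],
                         correct = corr[seq_len(i)],
                         is_reversal = isrev[seq_len(i)],
                         phase = phs[seq_len(i)])
    run <- structure(list(trials = trials, config = config), class = "staircase_run")
    run$reversal_deltas <- terminal_reversal_deltas(trials, config)
    run$jnd <- mean(run$reversal_deltas)
    run
  })
}

# A reversal is a pair of consecutive trials with opposite correctness; the
# index marks the switch-completing trial, but the delta attributed to the
# reversal is the one presented on the trial at which the track turned (the
# last trial of the old direction, index - 1). This pairs descending-track
# minima and ascending-track maxima symmetrically; attributing the
# completing trial's delta instead records ascending maxima a full up-step
# above the turn and biases the reversal mean upward by about
# (up_step - down_step)/2.
terminal_reversal_deltas <- function(trials, config) {
  rev_idx <- which(trials$is_reversal)
  k <- config$terminal_reversals
  if (length(rev_idx) < config$phase_switch_reversals + k)
    stop_vox("too few reversals to estimate a JND", "voxpitch_insufficient_data")
  trials$delta[rev_idx[(length(rev_idx) - k + 1):length(rev_idx)] - 1L]
}

#' Estimate the JND from a completed staircase run
#'
#' Arithmetic mean of the stimulus differences attributed to the final
#' `terminal_reversals` reversals. A reversal spans two consecutive trials
#' with opposite correctness; the attributed difference is the one presented
#' on the trial at which the track turned (the first trial of the pair),
#' which keeps the estimator centred on the staircase's equilibrium
#' (the 75%-correct point for both built-in configurations).
#'
#' @param run A `staircase_run`, or a trial data frame with `delta` and
#'   `correct` columns (reversals are then re-derived with
#'   [detect_reversals()]).
#' @param config The [staircase_config()] (taken from the run if omitted).
#' @return The JND estimate, in the units of the difference scale.
#' @export
estimate_jnd <- function(run, config = NULL) {
  if (inherits(run, "staircase_run")) {
    trials <- run$trials
    config <- config %||% run$config
  } else {
    trials <- as.data.frame(run)
    stopifnot(!is.null(config), all(c("delta", "correct") %in% names(trials)))
    trials$is_reversal <- seq_len(nrow(trials)) %in% detect_reversals(trials$correct)
  }
  mean(terminal_reversal_deltas(trials, config))
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf(
    "Staircase run: %d trials, %d reversals, JND = %.3f\n",
    nrow(x$trials), sum(x$trials$is_reversal), x$jnd))
  invisible(x)
}

#' @export
plot.staircase_run <- function(x, ...) {
  tr <- x$trials
  graphics::plot(tr$index, tr$delta, type = "s", xlab = "Trial",
                 ylab = "Stimulus difference", ...)
  graphics::points(tr$index[tr$is_reversal], tr$delta[tr$is_reversal],
                   pch = 19, col = "firebrick")
  graphics::abline(h = x$jnd, lty = 2, col = "grey40")
  invisible(x)
}

#' Run a full discrimination test (several staircase runs)
#'
#' A test comprises `n_runs` staircase runs (one per vowel in the listening
#' experiment); the test-level JND is the mean of the per-run JNDs.
#'
#' @inheritParams run_staircase
#' @param n_runs Number of runs (default 5, one per vowel).
#' @return Object of class `staircase_test`: `run_results` (list of
#'   `staircase_run`), `jnds` (per-run estimates) and `jnd_mean`.
#' @export
run_test <- function(obs, config, n_runs = 5, seed = NULL) {
  stopifnot(n_runs >= 1)
  with_seed(seed, {
    runs <- lapply(seq_len(n_runs), function(i) run_staircase(obs, config))
    jnds <- vapply(runs, `[[`, numeric(1), "jnd")
    structure(list(run_results = runs, jnds = jnds, jnd_mean = mean(jnds),
                   config = config),
              class = "staircase_test")
  })
}

#' @export
print.staircase_test <- function(x, ...) {
  cat(sprintf("Discrimination test: %d runs, per-run JNDs %s; mean JND = %.3f\n",
              length(x$run_results),
              paste(sprintf("%.2f", x$jnds), collapse = ", "), x$jnd_mean))
  invisible(x)
}
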