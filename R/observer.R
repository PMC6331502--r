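# Parametric simulated observers for 2AFC discrimination. These replace human
# listeners for validating the staircase and for cohort simulation: each
# observer has a known psychometric function, so the staircase's convergence
# point can be checked against ground truth.

#' Construct a simulated 2AFC observer
#'
#' Two kinds are available:
#' * `"sigmoid"` — probability correct
#'   `P(delta) = 0.5 + (0.5 - lapse/2) * plogis(slope * (log(delta) - log(threshold)))`,
#'   a logistic psychometric function in log stimulus difference. The
#'   log-delta abscissa gives Weber-like (ratio-scale) behaviour, appropriate
#'   for pitch. The convention is `P(0) = 0.5` (chance) and
#'   `P(Inf) = 1 - lapse/2`.
#' * `"deterministic_threshold"` — correct iff `delta >= threshold`; useful
#'   for hand-checkable staircase tracks.
#'
#' @param kind `"sigmoid"` or `"deterministic_threshold"`.
#' @param threshold Stimulus difference at the function's inflection, in the
#'   same units as the staircase scale (cents or SER-%).
#' @param slope Steepness of the logistic in log-delta units.
#' @param lapse_rate Probability mass lost to lapses (0--0.1); at large delta
#'   the observer is correct with probability `1 - lapse_rate/2`.
#' @return Object of class `vox_observer`.
#' @seealso [p_correct()], [threshold_at()], [respond()]
#' @export
observer <- function(kind = c("sigmoid", "deterministic_threshold"),
                     threshold, slope = 8, lapse_rate = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold), threshold > 0)
  if (kind == "sigmoid")
    stopifnot(is.finite(slope), slope > 0,
              is.finite(lapse_rate), lapse_rate >= 0, lapse_rate <= 1)
  structure(list(kind = kind, threshold = threshold, slope = slope,
                 lapse_rate = lapse_rate, guess_rate = 0.5),
            class = "vox_observer")
}

#' @rdname observer
#' @param lapse Alias for `lapse_rate`.
#' @export
sigmoid_observer <- function(threshold, slope = 8, lapse = 0) {
  observer("sigmoid", threshold = threshold, slope = slope, lapse_rate = lapse)
}

#' @rdname observer
#' @export
threshold_observer <- function(threshold) {
  observer("deterministic_threshold", threshold = threshold)
}

#' @export
print.vox_observer <- function(x, ...) {
  if (x$kind == "sigmoid") {
    cat(sprintf(
      "Sigmoid 2AFC observer: threshold %.3g, slope %.3g, lapse %.3g (P75 at %.3g)\n",
      x$threshold, x$slope, x$lapse_rate, threshold_at(x, 0.75)))
  } else {
    cat(sprintf("Deterministic 2AFC observer: correct iff delta >= %.3g\n",
                x$threshold))
  }
  invisible(x)
}

#' Probability of a correct response at a stimulus difference
#'
#' @param obs A [observer()].
#' @param delta Stimulus difference(s), `>= 0`.
#' @return Probability in \[0.5 (approx.), 1\], monotone nondecreasing in
#'   `delta`.
#' @export
p_correct <- function(obs, delta) {
  stopifnot(inherits(obs, "vox_observer"), all(delta >= 0))
  if (obs$kind == "deterministic_threshold")
    return(as.numeric(delta >= obs$threshold))
  psi <- ifelse(delta == 0, 0,
                stats::plogis(obs$slope * (log(delta) - log(obs$threshold))))
  0.5 + (0.5 - obs$lapse_rate / 2) * psi
}

#' Stimulus difference at which the observer reaches a target probability
#'
#' Analytic inverse of [p_correct()] for sigmoid observers; for deterministic
#' observers the threshold itself is returned (the step function attains any
#' probability in (0.5, 1\] there under the staircase's equilibrium
#' semantics).
#'
#' @param obs A [observer()].
#' @param p Target probability, strictly between 0.5 and `1 - lapse_rate/2`.
#' @return Stimulus difference with `p_correct(obs, .) == p` (to within 1e-9
#'   for sigmoid observers).
#' @export
threshold_at <- function(obs, p = 0.75) {
  stopifnot(inherits(obs, "vox_observer"), length(p) == 1L, is.finite(p))
  if (obs$kind == "deterministic_threshold") {
    if (p <= 0.5 || p > 1)
      stop_vox("target probability not achievable", "voxpitch_invalid_argument")
    return(obs$threshold)
  }
  ceiling_p <- 1 - obs$lapse_rate / 2
  if (p <= 0.5 || p >= ceiling_p)
    stop_vox(sprintf("target probability must lie strictly in (0.5, %.4g)",
                     ceiling_p), "voxpitch_invalid_argument")
  psi <- (p - 0.5) / (0.5 - obs$lapse_rate / 2)
  obs$threshold * exp(stats::qlogis(psi) / obs$slope)
}

#' Simulate a single 2AFC response
#'
#' The observer is correct with probability [p_correct()]; a correct response
#' selects the interval holding the manipulated stimulus, an incorrect one
#' the other interval.
#'
#' @param obs A [observer()].
#' @param delta Stimulus difference presented.
#' @param manipulated_interval Which interval (1 or 2) holds the manipulated
#'   stimulus.
#' @param seed Optional seed for a self-contained draw; by default the current
#'   RNG stream is used (as inside [run_staircase()]).
#' @return Chosen interval, 1 or 2.
#' @export
respond <- function(obs, delta, manipulated_interval, seed = NULL) {
  stopifnot(manipulated_interval %in% c(1L, 2L))
  with_seed(seed, {
    correct <- stats::runif(1) < p_correct(obs, delta)
    if (correct) as.integer(manipulated_interval)
    else as.integer(3L - manipulated_interval)
  })
}

#' Parse an observer specification string
#'
#' Accepts the compact form used in configuration files, e.g.
#' `"sigmoid:thresh=40,slope=8,lapse=0.02"` or `"deterministic:thresh=50"`.
#'
#' @param text Specification string.
#' @return A [observer()].
#' @export
parse_observer <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop_vox("observer spec must look like 'sigmoid:thresh=40,slope=8'",
             "voxpitch_invalid_argument")
  kind <- match.arg(parts[1], c("sigmoid", "deterministic", "deterministic_threshold"))
  kv <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
    vapply(kv, `[`, character(1), 1))
  if (kind == "sigmoid") {
    sigmoid_observer(threshold = vals[["thresh"]],
                     slope = if ("slope" %in% names(vals)) vals[["slope"]] else 8,
                     lapse = if ("lapse" %in% names(vals)) vals[["lapse"]] else 0)
  } else {
    threshold_observer(vals[["thresh"]])
  }
}
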