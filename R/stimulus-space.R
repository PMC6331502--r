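# Stimulus parameter space for the two discrimination tests: fundamental
# frequency (F0) in musical cents around a 112 Hz baseline (vocal pitch), and
# the spectral envelope ratio (SER) simulating vocal-tract-length change
# (vocal timbre), plus a source-filter vowel synthesizer for demo fixtures.

PITCH_BASE_HZ <- 112
PITCH_BASE_CENTS <- 1200
PITCH_CENTS_RANGE <- c(0, 2400)
SER_RANGE <- c(0.80, 1.30)
VOWELS <- c("a", "e", "i", "o", "u")

# Three-formant table per vowel (Hz): classic adult-male values. Only the
# relative scaling by SER matters for the discrimination tests; the absolute
# values are documented package constants.
VOWEL_FORMANTS <- rbind(
  a = c(730, 1090, 2440),
  e = c(530, 1840, 2480),
  i = c(270, 2290, 3010),
  o = c(570,  840, 2410),
  u = c(300,  870, 2240)
)
colnames(VOWEL_FORMANTS) <- c("F1", "F2", "F3")

#' Convert a position on the musical-cent scale to frequency
#'
#' The pitch test expresses F0 manipulations in musical cents (100 cents =
#' 1 semitone, 1200 cents = 1 octave) around a baseline of 112 Hz placed at
#' 1200 cents, so the full 0--2400 cent scale spans one octave below to one
#' octave above the baseline.
#'
#' @param cents Position(s) on the cent scale.
#' @param base_hz Frequency anchored at `base_cents` (default 112 Hz).
#' @param base_cents Cent value of the anchor (default 1200).
#' @return Frequency in Hz: `base_hz * 2^((cents - base_cents)/1200)`.
#' @examples
#' cents_to_hz(1200)  # 112 Hz baseline
#' cents_to_hz(2400)  # one octave up: 224 Hz
#' @seealso [hz_to_cents()]
#' @export
cents_to_hz <- function(cents, base_hz = PITCH_BASE_HZ,
                        base_cents = PITCH_BASE_CENTS) {
  if (!all(is.finite(cents)) || !all(is.finite(base_hz)) ||
      !all(is.finite(base_cents)))
    stop_vox("non-finite input to cents_to_hz()", "voxpitch_invalid_argument")
  if (any(base_hz <= 0))
    stop_vox("base_hz must be positive", "voxpitch_invalid_argument")
  base_hz * 2^((cents - base_cents) / 1200)
}

#' Convert frequency to a position on the musical-cent scale
#'
#' Inverse of [cents_to_hz()]; round-trips to within 1e-9 cents.
#'
#' @param hz Frequency in Hz (> 0).
#' @inheritParams cents_to_hz
#' @return Position on the cent scale.
#' @export
hz_to_cents <- function(hz, base_hz = PITCH_BASE_HZ,
                        base_cents = PITCH_BASE_CENTS) {
  if (!all(is.finite(hz)) || any(hz <= 0) || any(base_hz <= 0))
    stop_vox("frequencies must be finite and positive",
             "voxpitch_invalid_argument")
  base_cents + 1200 * log2(hz / base_hz)
}

#' Formant frequencies of a vowel under spectral-envelope scaling
#'
#' @param vowel One of `"a"`, `"e"`, `"i"`, `"o"`, `"u"`.
#' @param ser Spectral envelope ratio; 1.0 is the unmodified envelope.
#'   Scaling the envelope in log-frequency multiplies every formant by `ser`.
#' @return Named numeric vector of three formant frequencies (Hz).
#' @export
formant_frequencies <- function(vowel, ser = 1.0) {
  vowel <- match.arg(vowel, VOWELS)
  stopifnot(is.numeric(ser), length(ser) == 1L, is.finite(ser), ser > 0)
  VOWEL_FORMANTS[vowel, ] * ser
}

#' Enumerate the stimulus set of a discrimination test
#'
#' The pitch test manipulates F0 in 1-cent steps over (0, 2400] cents for each
#' of the five vowels (2400 values per vowel, 12,000 stimuli in total); the
#' timbre test manipulates SER in 0.001 steps over \[0.80, 1.30\] (501 values
#' per vowel, 2,505 in total).
#'
#' @param test `"pitch"` or `"timbre"`.
#' @param vowels Vowels to include (default all five).
#' @return A data frame with columns `id`, `vowel`, and `cents`/`hz` (pitch)
#'   or `ser` (timbre).
#' @export
enumerate_stimulus_set <- function(test = c("pitch", "timbre"),
                                   vowels = VOWELS) {
  test <- match.arg(test)
  vowels <- match.arg(vowels, VOWELS, several.ok = TRUE)
  if (test == "pitch") {
    grid <- seq_len(2400)
    out <- expand.grid(cents = grid, vowel = vowels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$hz <- cents_to_hz(out$cents)
    out$id <- sprintf("pitch_%s_%04d", out$vowel, out$cents)
  } else {
    grid <- round(seq(SER_RANGE[1], SER_RANGE[2], by = 0.001), 3)
    out <- expand.grid(ser = grid, vowel = vowels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$id <- sprintf("timbre_%s_%0.3f", out$vowel, out$ser)
  }
  out[, c("id", "vowel", setdiff(names(out), c("id", "vowel")))]
}

#' Specify a vowel stimulus
#'
#' Duration (600 ms), sampling rate (44,100 Hz) and target RMS amplitude
#' (0.05) are the fixed values used throughout the test battery.
#'
#' @param vowel One of the five vowels.
#' @param cents F0 position on the cent scale, within \[0, 2400\].
#' @param ser Spectral envelope ratio within \[0.80, 1.30\].
#' @param duration_ms Stimulus duration in milliseconds.
#' @param sample_rate_hz Sampling rate.
#' @param target_rms Target root-mean-square amplitude.
#' @return An object of class `vowel_spec`.
#' @export
vowel_spec <- function(vowel, cents = PITCH_BASE_CENTS, ser = 1.0,
                       duration_ms = 600, sample_rate_hz = 44100,
                       target_rms = 0.05) {
  vowel <- match.arg(vowel, VOWELS)
  stopifnot(is.numeric(cents), length(cents) == 1L, is.finite(cents),
            is.numeric(ser), length(ser) == 1L, is.finite(ser))
  if (cents < PITCH_CENTS_RANGE[1] || cents > PITCH_CENTS_RANGE[2])
    stop_vox("cents outside [0, 2400]", "voxpitch_invalid_argument")
  if (ser < SER_RANGE[1] || ser > SER_RANGE[2])
    stop_vox("ser outside [0.80, 1.30]", "voxpitch_invalid_argument")
  structure(list(vowel = vowel, cents = cents, hz = cents_to_hz(cents),
                 ser = ser, duration_ms = duration_ms,
                 sample_rate_hz = sample_rate_hz, target_rms = target_rms),
            class = "vowel_spec")
}

#' @export
print.vowel_spec <- function(x, ...) {
  cat(sprintf("Vowel /%s/: F0 %.2f Hz (%.0f cents), SER %.3f, %d ms @ %d Hz\n",
              x$vowel, x$hz, x$cents, x$ser, x$duration_ms, x$sample_rate_hz))
  invisible(x)
}

# Log-amplitude spectral envelope: Gaussian formant bumps over a small floor.
# Gaussian bumps make the log-amplitude locally parabolic around each formant,
# so spectral peak positions are recoverable essentially exactly by parabolic
# interpolation on harmonic amplitudes.
formant_envelope <- function(freq, formants,
                             gains = c(1.0, 0.5, 0.25),
                             widths = c(60, 80, 100), floor_amp = 1e-3) {
  amp <- rep(floor_amp, length(freq))
  for (j in seq_along(formants)) {
    amp <- amp + gains[j] * exp(-(freq - formants[j])^2 / (2 * widths[j]^2))
  }
  amp
}

#' Synthesize a vowel waveform
#'
#' A source-filter surrogate: a harmonic source at the requested F0 (all
#' harmonics in cosine phase, i.e. a band-limited pulse train) shaped by a
#' three-formant spectral envelope whose centre frequencies are the vowel's
#' table values multiplied by `ser`. The waveform is normalized to the target
#' RMS. This is a deliberately simple, verifiable stand-in for full
#' analysis-resynthesis of natural vowels.
#'
#' @param spec A [vowel_spec()].
#' @param max_harmonic_hz Highest harmonic to include (default 6 kHz; the
#'   envelope is at floor level well below this).
#' @return Numeric waveform of length `duration_ms/1000 * sample_rate_hz`,
#'   with attributes `sample_rate_hz` and `spec`.
#' @examples
#' w <- synthesize_vowel(vowel_spec("a", cents = 1200))
#' sqrt(mean(w^2))  # 0.05
#' @export
synthesize_vowel <- function(spec, max_harmonic_hz = 6000) {
  stopifnot(inherits(spec, "vowel_spec"))
  sr <- spec$sample_rate_hz
  nyq <- sr / 2
  formants <- formant_frequencies(spec$vowel, spec$ser)
  widths <- c(60, 80, 100)
  if (max(formants + 3 * widths) > nyq)
    stop_vox(sprintf(
      "SER scaling pushes a formant (%.0f Hz) too close to Nyquist (%.0f Hz)",
      max(formants), nyq), "voxpitch_nyquist")
  f0 <- spec$hz
  n <- round(spec$duration_ms / 1000 * sr)
  k <- seq_len(floor(min(max_harmonic_hz, nyq - 1) / f0))
  fk <- k * f0
  amps <- formant_envelope(fk, formants, widths = widths)
  t <- (seq_len(n) - 1) / sr
  wave <- as.numeric(cos(outer(t, 2 * pi * fk)) %*% amps)
  wave <- wave * (spec$target_rms / sqrt(mean(wave^2)))
  attr(wave, "sample_rate_hz") <- sr
  attr(wave, "spec") <- spec
  wave
}

#' Estimate the fundamental frequency of a waveform by autocorrelation
#'
#' Normalized FFT-based autocorrelation with parabolic interpolation around
#' the period peak; octave errors are avoided by taking the shortest lag whose
#' peak is within 10% of the global maximum in the search range.
#'
#' @param wave Numeric waveform.
#' @param sample_rate_hz Sampling rate (taken from the waveform attribute if
#'   present).
#' @param f_min,f_max Search range in Hz.
#' @return Estimated F0 in Hz.
#' @export
estimate_f0 <- function(wave, sample_rate_hz = attr(wave, "sample_rate_hz"),
                        f_min = 60, f_max = 500) {
  stopifnot(is.numeric(wave), length(wave) > 0, !is.null(sample_rate_hz))
  x <- wave - mean(wave)
  n <- length(x)
  m <- 2^ceiling(log2(2 * n))
  sp <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(sp)^2, inverse = TRUE))[seq_len(n)]
  ac <- ac / ac[1]
  lag_min <- max(2L, floor(sample_rate_hz / f_max))
  lag_max <- min(n - 2L, ceiling(sample_rate_hz / f_min))
  lags <- lag_min:lag_max
  vals <- ac[lags + 1L]
  # local maxima: vals[i] > vals[i-1] and vals[i] >= vals[i+1]
  interior <- 2:(length(vals) - 1)
  peak_idx <- interior[vals[interior] > vals[interior - 1] &
                         vals[interior] >= vals[interior + 1]]
  if (length(peak_idx) == 0) peak_idx <- which.max(vals)
  best <- max(vals[peak_idx])
  lag0 <- lags[min(peak_idx[vals[peak_idx] >= 0.9 * best])]
  y1 <- ac[lag0]; y2 <- ac[lag0 + 1L]; y3 <- ac[lag0 + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
  sample_rate_hz / (lag0 + delta)
}

#' Estimate formant frequencies from a synthesized vowel
#'
#' Measures the amplitude of each harmonic of `f0` directly from the waveform
#' (discrete Fourier projection), finds local maxima of the log-amplitude
#' harmonic spectrum, and refines each peak by parabolic interpolation.
#'
#' @param wave Numeric waveform.
#' @param f0 Fundamental frequency in Hz (e.g. from [estimate_f0()]).
#' @param sample_rate_hz Sampling rate.
#' @param n_formants Number of formant peaks to return.
#' @param max_hz Upper frequency bound of the search.
#' @return Numeric vector of formant frequency estimates (Hz), ascending.
#' @export
estimate_formants <- function(wave, f0,
                              sample_rate_hz = attr(wave, "sample_rate_hz"),
                              n_formants = 3, max_hz = 4500) {
  stopifnot(is.numeric(wave), is.numeric(f0), f0 > 0)
  n <- length(wave)
  t <- (seq_len(n) - 1) / sample_rate_hz
  k <- seq_len(floor(max_hz / f0))
  fk <- k * f0
  # projection onto each harmonic (amplitude of cos+sin component)
  co <- crossprod(cos(2 * pi * outer(t, fk)), wave) * 2 / n
  si <- crossprod(sin(2 * pi * outer(t, fk)), wave) * 2 / n
  amp <- sqrt(co^2 + si^2)
  la <- log(pmax(amp, .Machine$double.xmin))
  interior <- 2:(length(la) - 1)
  peaks <- interior[la[interior] > la[interior - 1] &
                      la[interior] >= la[interior + 1]]
  if (length(peaks) < n_formants)
    stop_vox("fewer spectral peaks than requested formants",
             "voxpitch_peak_detection")
  peaks <- sort(peaks[order(la[peaks], decreasing = TRUE)][seq_len(n_formants)])
  vapply(peaks, function(i) {
    y1 <- la[i - 1]; y2 <- la[i]; y3 <- la[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
    (i + delta) * f0
  }, numeric(1))
}

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE writer (16-bit little-endian PCM, one channel). Samples
#' are clipped to \[-1, 1\] before quantization.
#'
#' @param wave Numeric waveform in \[-1, 1\].
#' @param path Output file path.
#' @param sample_rate_hz Sampling rate (taken from the waveform attribute if
#'   present, else 44100).
#' @return The path, invisibly.
#' @export
write_wav <- function(wave, path,
                      sample_rate_hz = attr(wave, "sample_rate_hz") %||% 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, as.numeric(wave))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  le <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeChar("RIFF", con, eos = NULL); le(36 + 2 * length(pcm), 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); le(16, 4)
  le(1, 2); le(1, 2)                       # PCM, mono
  le(sample_rate_hz, 4); le(sample_rate_hz * 2, 4)
  le(2, 2); le(16, 2)                      # block align, bits per sample
  writeChar("data", con, eos = NULL); le(2 * length(pcm), 4)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
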