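Package: voxpitch
Title: Adaptive Staircase Psychophysics for Vocal Pitch, Timbre and Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditory psychophysics of the voice: weighted one-up/one-down
    adaptive staircases with a reversal-mean just-noticeable-difference (JND)
    estimator on the musical-cent (fundamental frequency) and spectral-envelope-ratio
    (vocal-tract-length) scales; parametric simulated observers for two-alternative
    forced-choice discrimination; a source-filter vowel synthesizer with WAV export;
    scoring and confusion analysis of six-alternative vocal emotion recognition
    sessions; a statistical battery (pooled t-tests with Cohen's d, mixed
    repeated-measures ANOVA via the multivariate approach with partial eta squared,
    normality-gated correlations, Tukey-fence outlier screening, Fisher and Steiger
    Z comparisons of correlations, Bonferroni correction); and a matched-pair
    synthetic cohort generator so the full simulate-score-analyze pipeline runs
    end-to-end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
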