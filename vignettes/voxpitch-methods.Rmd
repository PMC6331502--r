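---
title: "Methods: adaptive staircases, simulated observers and the statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive staircases, simulated observers and the statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxpitch)
```

`voxpitch` implements the computational machinery of a matched-pair study of
vocal emotion recognition and voice-feature discrimination: the stimulus
parameter spaces, the adaptive threshold procedure and its JND estimator,
six-alternative emotion scoring, the statistical battery, and a synthetic
cohort generator that stands in for human participants. This vignette
documents the models, the tunable parameters, and the numerical and design
choices — including the places where the design was genuinely open and what
the simulations can and cannot establish about real data.

## The stimulus spaces

**Vocal pitch.** F0 manipulations are expressed in musical cents
(100 cents = 1 semitone, 1200 cents = 1 octave): a scale position of
$c$ cents maps to $f = 112 \cdot 2^{(c - 1200)/1200}$ Hz, so the 0–2400 cent
grid spans one octave below to one octave above the 112 Hz male-voice
baseline. At 1-cent steps this gives 2,400 manipulations per vowel and
12,000 stimuli over the five vowels /a/, /e/, /i/, /o/, /u/. (We interpret
the grid as 2,400 points per vowel — i.e. excluding one endpoint — because
that is the reading consistent with the published 12,000-sound total; the
inclusive count would give 2,401.)

**Vocal timbre.** The spectral envelope ratio (SER) scales the spectral
envelope in log-frequency, which multiplies every formant frequency by the
SER and is perceived as a change in speaker size. The grid runs from 0.80 to
1.30 in 0.001 steps: 501 values per vowel, 2,505 stimuli in total. The
published total for the timbre set is also 12,000, which is not consistent
with a 0.001-step lattice on [0.80, 1.30]; we report the lattice count and
leave the discrepancy unreconciled.

**Vowel synthesis.** `synthesize_vowel()` is a source-filter *surrogate*,
not an analysis–resynthesis system: a harmonic source at the requested F0
(all harmonics in cosine phase, a band-limited pulse train) is shaped by a
three-formant envelope and normalized to RMS 0.05. Formant tables are fixed
package constants (classic adult-male values); only their *relative* scaling
by the SER matters for the discrimination tests. The envelope is a sum of
Gaussian bumps in amplitude, which makes the log-amplitude spectrum locally
parabolic around each formant — so the verification path
(`estimate_formants()`: harmonic amplitudes by Fourier projection, peak
refinement by parabolic interpolation) recovers formant centres essentially
exactly when the harmonic spacing samples the envelope finely enough
(F0 ≲ 130 Hz; at one octave above baseline the harmonic grid genuinely
undersamples an 60–100 Hz-wide formant, a physical limit, not an
implementation one). F0 is verified by normalized autocorrelation with
parabolic lag interpolation, taking the shortest lag within 10% of the
global maximum to avoid octave errors. If an SER scaling would push a
formant against the Nyquist frequency the synthesizer fails loudly rather
than alias. None of this claims perceptual naturalness; the synthesizer
exists so that the full stimulus → staircase → statistics chain can be
exercised and audited.

## Simulated observers

Observers implement a two-interval forced-choice (2AFC) psychometric
function in *log* stimulus difference,

$$P(\text{correct} \mid \Delta) = \tfrac12 + \left(\tfrac12 -
\tfrac{\lambda}{2}\right)\,\mathrm{logis}\!\big(\beta\,(\log \Delta - \log
\theta)\big),$$

with threshold $\theta$ (same units as the staircase scale), slope $\beta$
and lapse rate $\lambda$. The log-Δ abscissa gives Weber-like behaviour,
appropriate for pitch discrimination, and fixes the conventions
$P(0) = 0.5$ (chance) and $P(\infty) = 1 - \lambda/2$ (lapses split evenly
between intervals). `threshold_at()` inverts the function analytically, so
the staircase's convergence target — the 75%-correct point — is available in
closed form. Defaults used in the pipeline are $\beta = 8$ and
$\lambda = 0.02$; a deterministic step-function observer is available for
hand-checkable staircase tracks.

## The staircase and its JND estimator

Both discrimination tests use the weighted one-up/one-down staircase: the
difference increases by $S_\text{up}$ after an incorrect response and
decreases by $S_\text{down}$ after a correct one, so the track equilibrates
where $S_\text{up}\,(1-p) = S_\text{down}\,p$, i.e.
$p = S_\text{up}/(S_\text{up}+S_\text{down}) = 0.75$ for both phase
configurations (30/10 → 6/2 cents for pitch; 3/1 → 0.6/0.2 SER percentage
points for timbre). A *reversal* is a switch in correctness across two
consecutive trials; after four reversals the fine (phase-2) steps take over,
and the run ends ten reversals later — 14 reversals at termination, always.
The JND is the mean difference over those final ten reversals, averaged over
five runs.

**Reversal value attribution.** The published procedure says the JND is
estimated "from all" differences at the final ten reversals, which leaves
open *which* trial of the switch pair contributes its difference. The two
readings are not equivalent. Attributing the switch-completing trial records
descending-track minima at the turn but ascending-track maxima one full
up-step *above* the turn (after an error at $\Delta$, the next trial sits at
$\Delta + S_\text{up}$; if it is answered correctly, it completes the
reversal), which biases the reversal mean upward by roughly
$(S_\text{up}-S_\text{down})/2$ — about +2 cents for the pitch
configuration, large relative to the estimator's own replication SE.
Attributing instead the trial at which the track *turned* (the first trial
of the pair) pairs minima and maxima symmetrically; in simulation the
estimator is then centred on the observer's 75% point (measured bias
+0.002 cents at threshold 40 cents, −0.018 SER-points at threshold 4%,
against 3-SEM bands over 1,000 replicates). The package therefore uses
turn-trial attribution. Reversal *indices* still mark the switch-completing
trial, which is the natural definition for counting.

A small residual bias remains and grows with the observer's spread relative
to the step sizes (about +0.7 cents for a threshold of 65 cents at slope 8):
reversal-mean estimators are not exactly unbiased for any finite procedure.
The convergence tests quantify this under the study's configurations; users
simulating much shallower observers should expect visibly larger bias.

**Bounds and degeneracies.** The procedure as published does not say what
happens if the difference would leave the stimulus grid. We clamp to
[1, 2400] cents and [0.1, 30] SER-%; clamping can suppress a step but never
alters correctness bookkeeping. The manipulated stimulus is always *above*
the 112 Hz standard (the symmetric variant is unstated in the source
procedure); the interval holding it is randomized per trial, so chance is
exactly 0.5. A safety cap (default 10,000 trials) turns observers that never
reverse — e.g. a deterministic observer walked to the floor — into explicit
errors rather than hangs. Identical seeds give bit-identical runs.

## The emotion recognition task

Sessions are 120 six-alternative trials: each of happiness, sadness, fear,
anger, disgust and neutral presented 20 times, 10 per speaker.
`score_session()` returns per-emotion accuracies (the diagonal of the
row-normalized 6×6 confusion matrix) and the pooled total; under random
responding the expected total is 1/6. Stimulus covariates (emotional
intensity, i.e. independent-rater recognisability, and F0 frequency range)
are inputs, not computed quantities — their operational definitions live in
unavailable supplementary material, so the package takes them as per-stimulus
columns and constructs the four "very low / low / high / very high" levels
by quartile binning with ties resolved in stable trial-id order (an
assumption, documented as such).

## The statistical battery

All operations are pure functions over raw vectors or summary statistics:

* `pooled_t_and_d()` — the equal-variance two-sample t-test from group
  summaries, with Cohen's $d = (m_1 - m_2)/s_p$; with equal $n$ the pooled
  SD reduces to $\sqrt{(s_1^2+s_2^2)/2}$, which is what reproduces the
  published effect sizes. The identity $d = t\sqrt{1/n_1 + 1/n_2}$ holds on
  every result.
* `mixed_anova()` — the between-subjects effect is the one-way ANOVA on
  subject means (so with two groups $F = t^2$ exactly); the within-subject
  and interaction effects use the *multivariate* approach on the
  $(\text{levels}-1)$ successive difference scores: Wilks' $\Lambda$ with
  Rao's F (exact for one-df hypotheses), $df_1 = \text{levels}-1$,
  $df_2 = N - \text{groups} - \text{levels} + 2$. This is the approach whose
  degrees of freedom (5, 26 for a 2×6 design with 32 subjects) match the
  published ANOVA, rather than the univariate 5, 150. Partial eta squared is
  $1 - \Lambda = F\,df_1/(F\,df_1 + df_2)$. The univariate decomposition
  with Greenhouse–Geisser and Huynh–Feldt corrections is available as a
  secondary mode. Sum-to-zero group coding makes the within effect the test
  of the unweighted grand mean, as in standard statistical packages.
* `correlation()` — Pearson by default; Spearman when either variable fails
  Shapiro–Wilk at α = .05 (`gate = "auto"`). p-values use
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df for both methods (the
  t-approximation is what reproduces the published one-tailed p = .027 at
  r = −.489, n = 16); an exact permutation p for Spearman is available. For
  one-tailed tests the two-tailed p is halved only when the observed sign
  matches the pre-stated direction, else $1 - p/2$.
* `tukey_outliers()` — fences at 1.5 × IQR with Tukey hinges (the boxplot
  five-number summary); the weighted-average quantile definition used by
  some packages is a switch.
* `fisher_z()` / `steiger_z()` — comparisons of independent and dependent
  correlations on the Fisher $z$ scale. Steiger's test uses the
  pooled-estimate variant ($\bar r = (r_{12}+r_{13})/2$ in the covariance
  term), the form generally recommended for its null behaviour; both tests
  are verified by type-I-error calibration (empirical rejection ≈ .05 over
  10,000 null simulations) because the inter-correlation needed to reproduce
  the published dependent-comparison value is itself unpublished.
* `shapiro_wilk()`, `bonferroni()` — thin wrappers over the standard
  implementations (six-test Bonferroni threshold .0083, printed as .008).

## The synthetic cohort generator

The generator defines the study conditions: 16 ASD/comparison pairs matched
on gender (13 male / 3 female), handedness (14 right / 2 left), age
(≤ 3 years within pair) and full-scale IQ (≤ 15 points within pair), with
per-group means and SDs for the six emotion accuracies, the two JNDs,
non-vocal pitch accuracy, AQ and the ADOS communication score (ASD only)
taken from the published summary tables, and within-group correlation
targets of −.554/−.346 (emotion–pitch JND, comparison/ASD), −.501/−.197
(emotion–AQ) and −.672 (emotion–ADOS, ASD). Correlation targets not
published (emotion–timbre, emotion–non-vocal pitch) default to 0 and are
flagged in the spec object.

Construction is copula-style, because the source material gives only
marginal moments and a few pairwise correlations:

1. **Latent layer.** A standard-normal "ability" factor $a$ per participant;
   each per-emotion latent loads on $a$ with a common loading calibrated so
   the observed *total* (mean of the six transformed scores) has the target
   SD; every other measure loads on $a$ with a loading chosen to hit its
   target correlation with the total. A one-factor structure is always
   positive semidefinite, which matters because the published correlations,
   taken jointly with free cross-correlations, need not be.
2. **Marginal layer.** Latents map to observed scales through
   moment-matched transforms: scaled logit for percentage scales (bounded in
   [0, 100], or [0, 50] for AQ) with intercept and slope solved by nested
   root-finding on Gauss-type quadrature; lognormal (closed form) for JNDs
   and ADOS. Moments are therefore matched by construction, not by clamping.
3. **Attenuation compensation.** Nonlinear marginals attenuate latent
   correlations. To first Hermite order the attenuation factor of a
   transform $g$ is $\mathrm{Cov}(Z, g(Z))/\mathrm{SD}(g(Z))$ — available in
   closed form for the lognormal ($\sigma/\sqrt{e^{\sigma^2}-1}$) and by
   quadrature for the logit — and the latent loadings are divided by it, so
   *observed* correlations land on target (verified to within ±0.02 at
   pooled n = 20,000 per group).
4. **Screening.** Comparison-group AQ is capped below the clinical cutoff
   of 32, mirroring the study's inclusion screening.

Emotion sessions are generated per participant from their per-emotion
accuracy profile: trial-level Bernoulli responses, errors spread uniformly
over the five wrong categories unless a confusion kernel is supplied. An
optional intensity effect shifts trial-level log-odds by the stimulus's
*within-emotion* standardized intensity, so the per-emotion profile is
preserved in expectation (up to a small logistic-averaging term) while
harder stimuli within an emotion are recognised less often. Staircase
observers are derived so each participant's `threshold_at(0.75)` equals
their generated JND, making the cohort → staircase → statistics loop a true
round trip.

**What the simulations do and do not show.** Passing tests establish that
the procedures are implemented correctly and are internally consistent —
that the staircase recovers known thresholds, that the statistics reproduce
published values from published summaries, that the generator hits its
moments. They do not validate the one-factor dependence structure, the
marginal shapes, or the uniform confusion kernel as facts about real
listeners; those are modelling assumptions chosen for transparency, and real
data will differ (e.g. heavier-tailed JND distributions, structured
confusions between fear and sadness, floor effects in low-functioning
samples).

## Problem sizes and reproducibility

Simulation sizes used by the test suite and the acceptance script are chosen
to make Monte-Carlo error small relative to the quantity under test:
staircase convergence uses 1,000 replicate runs per configuration (3-SEM
bands of about ±0.4 cents / ±0.04 SER-points); type-I-error calibration uses
10,000 null datasets (±0.7 percentage points at 3 SE); cohort moment
recovery pools replicate cohorts of 500 pairs (2%-relative bands then sit at
roughly 3–5 MC standard errors even for the highest-variance measures);
session-total recovery uses 2,000 sessions per profile. Every stochastic
stage takes an explicit seed; the pipeline derives per-stage sub-seeds from
a single root seed, so any stage can be replayed in isolation and a
persisted configuration reproduces every output exactly.

## Known limitations

* The reversal-mean JND estimator retains a small positive bias that grows
  with observer spread relative to the step sizes; it is negligible at the
  study's configurations but not in general.
* The multivariate ANOVA requires more subjects than within-levels
  (difference-score covariance of full rank); designs with all-identical
  within-subject responses are rejected as rank deficient rather than
  reported as F = 0.
* The vowel synthesizer is a verification surrogate: harmonic-grid envelope
  sampling limits formant verification above F0 ≈ 130 Hz, and no claim of
  perceptual realism is made.
* Steiger's Z is validated by calibration, not against a published value,
  because the required inter-correlation is not published.
* The generator's matching constraints are satisfied by construction
  (shared pair deviates), which is stronger than the rejection-sampling a
  real recruitment process implies; pair-level covariance induced by
  matching is therefore idealized.
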