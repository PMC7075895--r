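---
title: "Methods: paired-contrast speech classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-contrast speech classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Psychoactive compounds change how people talk. Pitch and its stability,
the harmonics-to-noise ratio of the voice, pausing behaviour, lexical
richness, and the semantic content of spontaneous speech all shift under
acute intoxication, and those shifts are measurable from a microphone
recording and a transcript. The statistical obstacle is that
between-speaker variability in every one of these measures dwarfs the
within-speaker drug effect: a baseline pitch difference of 40 Hz between
two speakers is unremarkable, while a drug-induced shift of 5 Hz within
one speaker may be the entire signal.

`speechcontrast` implements an analysis built around within-participants
crossover designs, where every participant is recorded under every
condition (e.g. placebo and one or more active compounds). All inference
operates on *within-subject differences*, which removes the speaker
baseline exactly rather than trying to model it.

# Feature extraction

Each recording/transcript session is reduced to a fixed vector of 126
features in three domains:

* **88 acoustic features** (`A-` prefix), produced by
  `extract_acoustic()`: distributional descriptors (median,
  interquartile range, 5th/95th percentiles and their difference) of the
  fundamental-frequency track; jitter and shimmer in several standard
  variants (local, absolute, RAP/APQ-style smoothed quotients);
  harmonics-to-noise and noise-to-harmonics ratios; voice breaks; pause
  counts, durations and rates; speech and articulation rates from
  syllable nuclei; long-term average spectrum descriptors; 16 MFCC
  means; and formant vowel-space geometry (total convex-hull area, the
  /a/–/i/–/u/ triangle area via the shoelace formula on corner
  centroids, and the apex angle at /i/).
* **21 semantic features** (`S-` prefix), produced by
  `extract_semantic()`: for each of 21 target concepts, the median
  latent-semantic-analysis proximity between the concept vector and the
  content words of the transcript.
* **17 psycholinguistic features** (`P-` prefix), produced by
  `extract_psycholinguistic()`: token/type counts, type-token ratio,
  Honoré's statistic, Brunet's index, part-of-speech category rates,
  first-person-pronoun rate, filler rate, and propositional idea
  density (verbs, adjectives, adverbs, prepositions and conjunctions
  per token, with auxiliary-plus-participle constructions counted
  once).

## Acoustic processing choices

Recordings are preprocessed by `preprocess_audio()`: the first 30 s are
discarded (instruction and settling time), at most 4 minutes are
retained, annotated non-speech spans are removed, and recordings
shorter than 60 s are rejected rather than silently analysed.

Pitch is tracked by short-time normalized autocorrelation (40 ms
frames, 10 ms hop) with parabolic interpolation of the autocorrelation
peak. The peak *search* uses the biased autocorrelation estimator,
whose implicit `1 - lag/frame` taper penalizes octave-down candidates;
the *reported* peak value is then corrected by `flen/(flen - lag)` so
that a perfectly periodic signal scores r ≈ 1. Without this correction
the harmonics-to-noise ratio, `10·log10(r/(1-r))` averaged over voiced
frames, is biased several dB low for short periods relative to the
frame.

Jitter and shimmer are computed from glottal cycle marks found by
expected-period peak tracking inside voiced spans, with sub-sample
parabolic refinement. A robust glitch gate (5 × MAD around the median
period/amplitude, floored so that ordinary vocal variation is never
gated) excludes octave errors and span boundaries from the
perturbation statistics.

Formants are estimated by linear-prediction root-solving on a signal
decimated to a 10 kHz analysis band and pre-emphasized. The LPC order
is `4 + rate/1000` (14 at 10 kHz): `rate/1000` pole pairs cover the
formants below Nyquist, and the four extra coefficients let the model
absorb the residual glottal spectral tilt and the noise floor. With the
minimal order the tilt remnant splits F1 into two broad poles and the
sorted-pole assignment mistakes the second of them for F2; the larger
order removes this failure mode without affecting clean frames.

Pauses are silent runs of at least 0.3 s, found by intensity
thresholding 25 dB below the recording's peak intensity. Syllable
nuclei are intensity peaks separated by dips of at least 2 dB within
speech — the standard intensity-based nucleus rule — and feed the
speech-rate and articulation-rate features.

## Semantic model

`build_semantic_model()` builds a latent semantic space from a
reference corpus: a term–document matrix with `log(1 + count)` × entropy
term weighting, reduced by rank-`k` truncated SVD (default k = 100).
Concept–word proximity is the cosine between row vectors. The sign of
each singular vector is fixed by making its largest-magnitude entry
positive, which makes the embedding deterministic. `extract_semantic()`
reports, per concept, the median proximity over the transcript's
content words.

# Paired-contrast classification

For a condition pair (A, B) and one task, `make_contrasts()` builds for
every subject the two signed difference vectors `x_A - x_B` (label +1)
and `x_B - x_A` (label −1). The design is exactly symmetric about the
origin: the two samples of a subject are exact negations of each other.
Two consequences follow.

1. **Chance is exactly 50%.** Any classifier that is symmetric under
   negation of its input (all classifiers used here are trained on the
   symmetric set, so their decision rule is antisymmetric) classifies
   the two members of a pair consistently; under the null there is no
   information to separate +1 from −1, and expected accuracy is exactly
   one half — not approximately, which matters for calibration tests.
2. **Pairs must co-travel in cross-validation.** Splitting the two
   members of a pair across folds leaks the held-out subject's
   difference vector into training. All folds here are
   leave-one-*participant*-out: both samples of the held-out subject
   are removed together.

`nested_lopo_cv()` wraps this in nested cross-validation. The outer
loop holds out one participant. The inner loop, on the remaining
participants only, evaluates every combination of feature count
(Fibonacci-spaced grid 1, 2, 3, 5, 8, …, capped at the number of
features) and classifier configuration (linear SVM with cost in
{0.01, 0.1, 1, 10}; k-nearest-neighbour with k in {1, 3, 5}; random
forest) by leave-one-subject-out accuracy, and the winning cell is
refit on the full outer-training set and applied to the held-out
subject. Feature ranking (by Welch t statistic between classes,
computed on training data only, ties broken by name for determinism)
and standardization (training mean/sd, constant features dropped) are
refit inside every fold; nothing touches held-out data.

Tie-breaking in the inner loop is deterministic: highest accuracy,
then smallest feature count (parsimony), then classifier order
SVM < kNN < forest, then parameter order as listed.

## Numerical choices in the classifier stack

* The linear SVM is intercept-free: origin symmetry of the training
  set forces the optimal intercept to zero, so fitting without one
  loses nothing and guarantees an antisymmetric decision rule. It is
  fit by dual coordinate descent with a projected-gradient stopping
  rule (tolerance 1e-2 on the maximal KKT violation), which is far
  inside the accuracy-relevant regime for standardized inputs.
* Because the hinge losses of `(d, +1)` and `(-d, -1)` are identical
  for every weight vector, the SVM is actually fit on the positive
  half of the pairs at doubled cost — an exact equivalence (verified
  against a reference quadratic-programming implementation in the test
  suite) at half the problem size.
* kNN uses incrementally updated squared-distance matrices over the
  ranked-feature prefixes, so the feature-count grid costs one rank-1
  update per step instead of a full recomputation.
* The random forest uses 50 trees. Accuracy on these small paired
  designs is indistinguishable from much larger forests, and the inner
  selection loop fits thousands of forests per cross-validation run;
  the seed is derived deterministically per fold so runs are exactly
  reproducible.

`transfer_evaluate()` freezes a trained model (features,
standardization parameters, fitted classifier) and scores an external
cohort's contrasts, optionally after masking features that the
external cohort cannot provide (e.g. all acoustic features when only
transcripts exist); masking triggers a refit on the training contrasts
restricted to the surviving features, using the identical selection
procedure.

# Group-level inference

`wilcoxon_paired()` tests each feature's within-subject difference with
the paired Wilcoxon signed-rank test, using the exact null distribution
for n ≤ 25 pairs (important: with e.g. 5 subjects the smallest
achievable two-sided p is 1/16, and a normal approximation would
misstate it). `bh_fdr()` applies Benjamini–Hochberg step-up control
across the 126 features. `binomial_significance()` gives the exact
one-sided binomial tail for classification accuracy against chance
one-half. `partial_correlations()` estimates the feature association
structure with Schäfer–Strimmer-style shrinkage of the correlation
matrix toward the identity (analytic shrinkage intensity, so it is
well-conditioned even with more features than subjects), and
`mds_embed()` embeds a set of such matrices by classical
multidimensional scaling of their Frobenius distances, with a
deterministic sign convention.

# The synthetic cohort generator

Real dosing studies are small, slow and ethically constrained, so the
package treats its synthetic cohort generator as first-class,
fully-tested code: it is the instrument on which calibration, parameter
recovery, power and false-positive control are demonstrated.

## Voice synthesis

`synth_voice()` is a source-filter synthesizer: a glottal impulse train
with cycle-wise period perturbation (jitter) and amplitude perturbation
(shimmer), spectral tilt, filtered through cascades of three
second-order formant resonators cycling among /a/, /i/, /u/ targets at
the syllable rate, interleaved with log-normally distributed pauses
(median 0.5 s), over a −50 dB noise floor. Perturbation magnitudes are
calibrated so that the *realized* local jitter of the generated cycle
sequence matches the requested percentage in expectation (the
half-normal correction `σ = pct/100 · sqrt(π)/2` for the mean absolute
difference of consecutive periods). Vowel switches are crossfaded over
~15 ms with per-vowel loudness equalization and impulse-delay
alignment, because an abrupt or misaligned switch shifts the waveform
peak within a cycle and reads as spurious jitter. Intensity dips of
~9 dB over 60 ms at syllable boundaries give the intensity contour the
peak/dip structure that syllable-nucleus detection needs. Every
generated recording carries a `truth` record (realized jitter and
shimmer, pause intervals, f0) for recovery testing.

**Realism and limits.** The generator is deliberately the *simplest*
signal family on which every extracted feature is well defined — it is
a calibration instrument, not a speech synthesizer. Known limits:
vowel-transition frames produce formant values between targets;
realized shimmer as measured by the extraction stage runs 2–4
percentage points above the planted value (amplitude interaction
between the resonator decay and cycle-peak measurement), so shimmer is
exercised for monotonicity rather than absolute recovery; there are no
consonants, no prosodic f0 contours, and no channel/room effects.

## Transcript synthesis

`build_lexicon()` defines topic-structured vocabulary; `build_corpus()`
generates a reference corpus from it; `synth_transcript()` generates a
transcript as a mixture of a subject's background topic distribution
and a designated concept topic, with mixture weight `concept_weight`.
Raising the weight provably raises expected concept proximity in the
LSA space, which is the monotonicity property the tests check.

## Cohorts and planted effects

`cohort_config()` plus `generate_cohort()` produce a complete crossover
cohort: per subject × condition × task, a WAV file, a transcript, an
annotation file where the task has non-speech spans, and a manifest
row. Condition effects are planted through an `effect_map` that shifts
voice parameters (f0, jitter, shimmer, pause rate) and the concept
weight per condition. The default effect map's sizes are **synthetic
placeholders chosen to be plausible in direction**, not estimates from
any particular dataset; `null_effect_map()` plants nothing and is the
basis of all calibration claims.

For studies of the statistical machinery that do not need audio,
`simulate_feature_table()` skips synthesis and generates the 126
features directly: per subject a baseline N(0,1) per feature, a shift
on the treated condition for a seeded random subset of features, and
session noise scaled so the within-subject contrast has unit standard
deviation — making `effect_size` interpretable in contrast-sd units.

# Calibration properties the test suite enforces

* **Null calibration**: over 20 independent 30-subject null cohorts,
  mean nested cross-validated accuracy lies inside the Monte-Carlo 95%
  band around exactly 50% (the band conservatively counts one
  Bernoulli(½) draw per subject per cohort, since the two samples of a
  pair are dependent).
* **Closure**: every valid input yields exactly 88 acoustic and 21
  semantic features, by name.
* **Oracle equivalences**: Honoré, Brunet, exact Wilcoxon, exact
  binomial, Benjamini–Hochberg and shoelace-area values match
  hand-computed references to 1e-6 relative.
* **Parameter recovery**: planted f0 within 3 Hz, planted jitter
  within 0.5 percentage points, planted pause counts within ±1;
  semantic proximity increases monotonically in the concept weight.
* **Power**: accuracy grows with planted effect size and reaches 0.80
  at 2 contrast-sd with 30 subjects.
* **False-positive control**: under a 126-feature global null, the
  probability of any BH rejection at q = 0.05 stays at or below its
  nominal bound within Monte-Carlo error.
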