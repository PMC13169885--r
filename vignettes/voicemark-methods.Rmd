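---
title: "Speech and language biomarkers for BP/MDD group comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech and language biomarkers for BP/MDD group comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicemark)
```

## Overview

`voicemark` implements a speech-and-language biomarker pipeline for
differentiating bipolar disorder (BP) from major depressive disorder (MDD)
in euthymic (symptom-free) patients. Each subject contributes a short
(~60 s) monologue recording and its transcript. Five stages follow:

1. **Synthesis** — a cohort generator that produces audio, transcripts and
   demographics with known ground truth, so every downstream stage can be
   validated without clinical recordings (which are not publicly
   distributable in this domain).
2. **Acoustic extraction** — pause detection with a dB gate and
   minimum/maximum duration rules, plus peak/RMS amplitude statistics.
3. **Linguistic extraction** — part-of-speech frequencies, stop-word
   counts, TF-IDF keyword vectors.
4. **Sentiment extraction** — negation-aware lexicon polarity and emotion
   frequencies.
5. **Statistics and modeling** — Welch/chi-squared group comparisons under
   Benjamini–Hochberg FDR control, and a multi-classifier evaluation
   harness with stratified splitting, SMOTE and cross-validation.

The default study shape is two groups of 41 (BP) and 150 (MDD) subjects and
a feature matrix of 118 columns: 10 demographic, 13 part-of-speech, 75
TF-IDF keyword, 14 sentiment, and 6 acoustic variables.

## The acoustic model

### Pause detection

A *pause* is a meaningful interruption of speech, distinguished from the
brief articulatory gaps between words. The detector computes a short-window
RMS envelope (10 ms windows, 5 ms hop) and gates it at `threshold_db`
(default 35 dB) below the recording's reference level. A maximal
sub-threshold run is a pause if it lasts at least `min_ms` (200 ms);
silences shorter than roughly 150–200 ms are generally articulatory rather
than cognitively mediated, which motivates the floor. Each pause's
*credited* duration is capped at `max_ms` (500 ms), emulating a
silence-deletion workflow with a maximum deletion length: the cumulative
pause equals the original duration minus the silence-deleted duration.

Two interpretive choices deserve note, because desktop audio editors leave
them ambiguous:

* **Reference level.** The 35 dB gate is interpreted *relative to the
  recording's maximum short-window RMS*, not as an absolute dBFS level.
  Editor-style silence definitions are level-relative; an absolute
  interpretation would make the gate depend on recording gain. The
  reference is configurable.
* **Silences longer than the cap** are *counted at the cap*, not excluded.
  This follows from the subtraction construction of the cumulative pause.

The envelope parameters (10 ms window, 5 ms hop) resolve the 200 ms
minimum with at least 20 windows of context, and all synthesis is aligned
to the 5 ms hop grid so that inserted silences are measured without
boundary quantization.

The two derived ratios are `pause_per_duration` (cumulative pause over the
*original pause-intact* recording duration — "total speaking time" is read
as the full recording) and `pause_per_word` (cumulative pause over the
word count, in seconds per word).

### Amplitude statistics

Four statistics are reported: `max_peak = max(x)`, `min_peak = min(x)`,
`peak = max(|x|)` and `average_peak = RMS(x) × 1.414`. The 1.414 constant
is the crest factor of a sinusoid (peak = √2 × RMS); the package asserts
this identity in its tests. `peak` and `max_peak` are near-duplicates for
symmetric signals but both are reported, mirroring the conventional
feature table of this literature. Amplitudes are computed on the
(optionally noise-reduced) pause-intact signal.

### Noise reduction

An optional spectral gate estimates a noise magnitude profile from the
lowest-energy frames of the recording and subtracts it per frame (Hann
window, 20 ms frames, 5 ms hop, normalized overlap-add). It is **off by
default** because the synthetic signals are generated clean at a −80 dBFS
noise floor; it exists for recordings with broadband background noise and
is validated by checking that pause detection on a noisy-then-denoised
signal matches the clean-signal result.

## The linguistic model

Transcripts are whitespace-tokenized. The tagger is pluggable (any
function from text to token/tag pairs); the package ships a lookup tagger
driven by the synthetic vocabulary's tag table. Chinese segmentation is
deliberately not emulated — the pipeline's findings do not depend on a
specific tagger, and an adapter to any external segmenter can be plugged
in through the same interface.

Thirteen part-of-speech frequencies are reported (counts over total word
count): adjectives, conjunctions, adverbs, nouns, verbs, measure words,
prepositions, pronouns, time words, negations, and first-, second- and
third-person pronouns. Negations are counted by membership in a
configurable dictionary rather than by tag; person-pronoun splits likewise
use configurable lists. Numerals and particles, which appear in some POS
inventories, are not part of the canonical 13 and are not reported by
default.

### TF-IDF keywords

Stop words are counted, then removed; the TF-IDF model is fitted on the
filtered corpus. The weighting variant is the one used by the mainstream
machine-learning ecosystem: term frequency is the raw within-document
count divided by document length, and IDF is the smoothed
`log((1 + N) / (1 + df)) + 1` (an unsmoothed `log(N/df)` switch exists).
The keyword vocabulary is the top `k` terms by corpus-summed TF-IDF mass,
ties broken lexicographically, with `k = 75` by default and a supported
sweep range of 50–500. Two aggregate metrics accompany the vector: the
top-word sum (cumulative TF-IDF over the vocabulary) and the top-word sum
per word.

## The sentiment model

Per-word polarity follows the sign-flip rule
`Score(w) = Negation × Orientation(w)`, with `Negation = −1` when a
negation word occurs in the scope window immediately before the target
word and `+1` otherwise; out-of-lexicon words score 0. Scope is exactly
one preceding token by default (configurable); double negation within one
window flips once (a presence test, not a product of flips).

The aggregate polarity score of a text is the **mean** of per-word scores
over all tokens. The mean (rather than a raw sum) keeps the score in
[−1, 1] and independent of text length, which matches the magnitude
(~0.03) this literature reports for ~150-word monologues.

Annotation frequencies count lexicon hits per class (Positive, Neutral,
Negative, Non-opinionated, Not-a-word) over the total word count —
Not-a-word tokens stay in the denominator. The eight emotion frequencies
(anger, anticipation, disgust, fear, joy, sadness, surprise, trust) use a
negation-weighted count: a negated emotion token carries weight −1,
floored at zero *per token*, so it simply drops out of the reported
frequency (negating one of three joy tokens in a 100-word text yields
0.02). An absolute-count mode ignoring negation is available.

## Statistics

Continuous variables are compared with the two-sided Welch t-test — the
unequal-variance form is the right default for a 41 vs 150 design —
and categorical demographics with Pearson's chi-squared test (no
continuity correction; its type-I calibration at the cohort's sample sizes
is asserted by simulation). Group summaries print mean and IQR, and
medians are also retained, since both summary styles appear in this
literature's tables.

All p-values are adjusted with the Benjamini–Hochberg step-up procedure.
The FDR family **pools every compared variable across the four feature
families** — the comparisons are reported together, so the correction
should span them together; a per-family mode is available by flag.
Significance is declared at adjusted p < 0.05.

## The classification harness

The feature matrix keeps one column per demographic variable so that the
canonical 10/13/75/14/6 = 118 layout holds: binary variables are 0/1,
ordered categories (education, hospitalization recency) are ordinal codes,
and marital status uses documented integer codes (unmarried 0, married 1,
divorced 2). The alternative — one-hot expansion — would break the
118-column accounting, so it was not adopted.

Subjects are split 4:1 with stratification by label (8 BP subjects land in
the default test partition). SMOTE balances the training classes by
interpolating each synthetic row between a minority row and one of its
k = 5 nearest minority neighbours; it is applied **inside each
cross-validation fold** by default (the leakage-safe choice; a
once-globally mode exists for comparison) and never touches the test
partition — the harness asserts a content hash of the test rows before and
after training.

Training metrics are the arithmetic mean over 10 stratified CV folds;
test metrics come from the untouched holdout. BP is the positive class
throughout: sensitivity is the BP recall, and a degenerate always-positive
classifier shows sensitivity 1, specificity 0 and precision equal to the
test BP prevalence — a pattern the test suite reproduces explicitly as a
guard on the metric plumbing.

The default panel contains eight classifier families: decision tree
(rpart), k-nearest neighbours (z-scored features, k = 5), elastic-net
logistic regression (glmnet, inner 5-fold CV for the penalty), logistic
regression (glm), RBF support-vector machine (e1071, probability
estimates), Gaussian naive Bayes (e1071), random forest (randomForest,
500 trees) and gradient-boosted trees (xgboost, 100 rounds). The registry
is pluggable, and every run's report carries a lockfile pinning the
settings actually used, since library defaults drift across versions.
Feature importance is permutation-based: the mean AUC drop over repeated
permutations of each column, ranked descending with name tie-breaks.

## What the generator emulates — and what it does not

The synthetic cohort generator exists to give every stage a measurable
ground truth. Voiced segments are harmonic bursts (a fundamental drawn in
120–220 Hz plus two overtones) with per-segment amplitudes drawn from the
group's amplitude distribution; true silences sit at a −80 dBFS noise
floor, far below the 35 dB gate, so the detector's behaviour is
unambiguous. Silence lengths are drawn (250–450 ms by default) until the
target pause fraction is met, the last silence being truncated so the
truth hits the target exactly. Transcripts are whitespace-delimited
pseudo-words whose part-of-speech category and lexicon class are drawn
independently, with negation tokens inserted before content words at the
configured rate.

Group calibration is directional, not a reproduction of any clinical
dataset: BP pause fraction centred at 0.19 vs MDD at 0.30; BP word count
centred at 201 vs MDD at 146; MDD amplitude mean and spread larger than
BP's; demographic tables follow the published cohort's proportions
(e.g. BP hospitalization history skewed toward past admissions). The
spreads are calibration choices — this literature reports IQRs but no
within-group variance model, so the generator's standard deviations are
free parameters chosen to look like plausible clinical heterogeneity.

Passing tests on synthetic cohorts therefore demonstrate that the
*extractors and statistics recover known ground truth and hold their
nominal error rates* — not that the package reproduces any clinical
effect size. Real speech differs in ways the generator does not attempt:
phonetics, speaker identity, articulatory gap structure, ASR transcription
errors, and the coupling between what is said and how it sounds.

## Numerical choices and degenerate inputs

* All synthesis durations are rounded to the 5 ms envelope grid; pause
  measurement then has no boundary quantization against the detector.
* Duration comparisons in the detector use a 1e-9 s slack so that
  grid-aligned silences of exactly 200 ms are admitted.
* Zero word count or zero duration raises an `undefined-feature error`
  rather than silently producing NaN; assembly aborts with the subject id.
* A waveform shorter than one analysis window contains no pauses (not an
  error); non-finite samples are an input error.
* Both-groups-constant comparisons return p = 1 (equal means) or 0;
  degenerate contingency margins are a test error.
* TF-IDF ties are broken lexicographically; requesting more keywords than
  distinct terms keeps all terms with a warning.
* SMOTE reduces k with a warning when the minority class has at most k
  members.

## Problem sizes used by the validation suite

The test suite and reproduction script run at desk scale by design: the
structural checks use the full default cohort (191 subjects, ~60 s audio
each, about 20 s of compute); parameter-recovery checks use 50-subject
cohorts with point-mass pause fractions (0.19 vs 0.30, recovered within
±0.02 and flagged significant after FDR); statistical calibration uses
10,000 null replicates per test and 2,000 all-null BH families; harness
calibration uses 50 label-shuffled seeds with a fast classifier. Unit
tests use smaller cohorts (5–25 subjects, 5–10 s audio) to keep the suite
fast.

## Known limitations

* The generator's voiced/silence alternation is far cleaner than real
  speech; detector performance on real recordings will depend on the
  noise-reduction stage and the relative-reference interpretation of the
  gate.
* The identity tagger sidesteps segmentation entirely; POS features on
  real Chinese text require an external segmenter behind the tagger
  interface.
* `peak` and `max_peak` are redundant for symmetric synthetic signals.
* The harness evaluates a small test partition (39 subjects, 8 BP) under
  the default shape; per-classifier test metrics are accordingly noisy,
  which is precisely why the suite checks calibration properties rather
  than headline AUCs.
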