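---
title: "Scoring sung recall and singing accuracy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sung recall and singing accuracy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(singrec)
```

This vignette documents the models implemented by `singrec`, the parameter
choices that matter, what the synthetic-data generators emulate, and the
numerical decisions taken where the design was genuinely open.

## The measurement problem

Sung production data is "dirty": a participant sings into a consumer
microphone, a probabilistic tracker (pYIN-style) transcribes the audio into
note events (onset, duration, f0) or a frame-level pitch track, and the
transcription must then be scored against a target. Two families of
measures address two different constructs:

* **Melodic recall** — how much of the melody, as a structured object, was
  reproduced. Scored by melodic *similarity*, which tolerates insertions,
  deletions and length differences.
* **Singing accuracy** — how precisely individual pitches and intervals
  were produced. Scored in cents against positionally aligned targets.

`singrec` keeps the two families deliberately independent: the accuracy
measures use positional (index-by-index) alignment and never edit-based
alignment, which belongs to the similarity family.

## Melodic similarity: opti3

The trial outcome for melody singing is

$$\mathrm{opti3} = 3.027\,\mathrm{ngrukkon} + 2.502\,\mathrm{rhythfuzz} + 1.439\,\mathrm{harmcore},$$

with weights estimated from perceptual similarity ratings in prior work and
embedded as constants (`similarity_weights()`).

* `ngrukkon(a, b, n = 3)` — Ukkonen similarity over interval n-gram count
  profiles: $1 - \sum_\tau |f_a(\tau) - f_b(\tau)| / (N_a + N_b)$, where
  $N_x$ counts the n-gram tokens of melody $x$. Intervals make it
  transposition invariant; a 14-semitone leap is *not* reduced modulo the
  octave. The default n-gram length is 3, with an automatic fallback to the
  shorter melody's interval count so 2–3-note items remain scorable, and an
  option to average over n = 3..8 (the production setting is not pinned
  down in the literature; the single-n default is documented and
  configurable).
* `rhythfuzz(a, b)` — durations are "fuzzified" into five classes (very
  short … very long) by the log2 ratio to the melody's *median* duration
  with boundaries at −1.5, −0.5, +0.5, +1.5, then compared by
  length-normalized edit similarity. Median-relative classes make the
  measure tempo invariant. One consequence worth knowing: a two-note melody
  is always symmetric about its median, so its class string can never be
  (medium, long).
* `harmcore(a, b)` — each melody is segmented into contiguous 2 s windows
  (two beats at the nominal tempo; eight notes of a 250 ms/note arhythmic
  item), each window's duration-weighted pitch-class profile is correlated
  with the 24 rotated Krumhansl–Kessler probe-tone profiles, and the
  best-key label sequences are compared by edit similarity. Bar structure
  is unavailable for arhythmic stimuli, so fixed time windows are used for
  both trial types; the window length is a configuration knob.

**Normalization.** The raw weighted sum is 6.968 at identity, yet sung
recall outcomes are modelled on [0, 1] (the fitted intercepts of the trial
models are 0.37–0.74). `opti3()` therefore divides by the weight sum by
default; `normalize = FALSE` recovers the raw sum.

**Ties and equivariance.** The best key per window is the correlation
argmax with a deterministic tie-break (major before minor, then lowest
pitch class). At an *exact* correlation tie no fixed tie-break can commute
with transposition, so strict rotation-equivariance of `harmcore` holds
only away from ties. Ties require special profile symmetries and have
probability zero for generic (continuous) durations; with coarse duration
grids they occur in roughly 0.3% of random pairs. A perfectly uniform
pitch-class profile (e.g. a chromatic scale in equal durations) has zero
variance and no defined key correlation at all; `tonalness()` signals this
case. A single-pitch-class melody, by contrast, has a spiky profile and a
perfectly defined (if weak) correlation.

## Singing accuracy measures

For a target and a sung melody aligned index-by-index up to the shorter
length, all in cents:

* note accuracy — mean |sung − target| MIDI × 100;
* note precision — mean, over target pitches occurring ≥ 2 times, of the SD
  of the sung pitches produced for that target (undefined when no pitch
  recurs, reported as missing);
* interval accuracy/precision — the same definitions on successive
  unrounded interval sequences, which removes any constant transposition
  error;
* proportion of correct note events — the share of sung notes whose
  rounded MIDI pitch is contained in the target's rounded pitch set. This
  is the rehearsal-paradigm outcome: it is order-insensitive and penalizes
  incidental singing. Membership uses absolute MIDI because stimuli are
  transposed into the singer's range before presentation; an
  octave-equivalence flag exists but is off by default.

Cents (scale-free) rather than Hz deviations are used throughout, and
rounding is always half-away-from-zero (`round_half_away()`), so "correct
note" judgements do not depend on the parity behaviour of banker's
rounding.

## Long-note measures

From the voiced frames of a sustained-note track (by default smoothed with
a 5-frame running median — robust, deterministic, and an adequate stand-in
for a tracker's internal smoothing, which is not otherwise specified):

| measure | definition |
|---|---|
| accuracy | mean absolute cents deviation from the target |
| var | variance of f0 in Hz² (computed on the smoothed track; a flag restores raw) |
| dtw_distance | DTW (absolute-difference cost) between the cents-deviation series and an equal-length all-zero series, divided by the warping-path length |
| autocorrelation_mean | mean sample autocorrelation over lags 1..⌊L/2⌋ |
| run_test | Wald–Wolfowitz runs z about the track median (median-equal values dropped; missing for a constant track) |
| no_cpts | PELT mean-shift changepoint count |
| beginning_of_second_cpt | time (s) at which the second changed segment begins; missing with < 2 changepoints |

Path-length normalization of the DTW distance removes the trivial
dependence on trial duration. Against a flat reference the optimal path is
the diagonal, so this measure coincides with `accuracy` for clean tracks —
they diverge only under octave glitches and other local structure, which is
also why both are retained (they load on the same composite component).

**Changepoints.** Segmentation is exact PELT over a scaled residual
sum-of-squares cost with an MBIC-style per-changepoint penalty of
`3·log(n)`, following the defaults of the standard mean-shift changepoint
routine this mirrors. Two numerical details: the series is mean-centred
before the cumulative-sum cost is formed (otherwise the quadratic terms
cancel catastrophically for near-constant tracks at ~260 Hz), and the noise
scale is estimated from median absolute differences at a lag *beyond the
smoothing window* — lag-1 differences of a running-median-smoothed series
understate the marginal noise several-fold and cause gross
over-segmentation. A constant series is returned unsegmented. Early second
changepoints indicate onset "scoop" (starting flat and gliding up to
pitch); in directional comparisons, tracks without a second changepoint are
censored at the trial duration, which is conservative for the tested
direction.

Per-trial measures are averaged field-wise across a participant's trials,
ignoring missing values and retaining the per-field contributing count.

## Melodic features and the item bank

Item difficulty is modelled from five melodic features plus length:

* `i_entropy` — Shannon entropy (log2) of the interval distribution,
  clamped to ±12 semitones (25 classes) and normalized by log2(25);
* `d_entropy` — normalized entropy of the five duration classes;
* `tonalness` — the maximum of the 24 key-profile correlations;
* `step_cont_loc_var` — the melody rendered as a duration-weighted step
  function of MIDI pitch, sampled at 64 equidistant points (the convention
  of the feature-extraction literature this feature comes from); the value
  is the mean absolute difference of adjacent samples. At fixed sampling
  this equals (total absolute step size)/63 whenever note boundaries are at
  least one sample gap apart; note that the value is tied to the 64-point
  convention — it shrinks as the sampling is refined, so the sample count
  is part of the feature definition rather than a numerical tolerance;
* `log_freq` — natural log of the relative frequency of the item's
  interval sequence among all corpus n-grams of its length, with 0.5-count
  smoothing for unseen items.

`build_item_bank()` tokenizes a monophonic corpus into every contiguous
sub-melody of 3–15 notes (15 notes being the conventional upper bound for
short-term memory of unknown melodies), deduplicates on interval identity —
the transposition-robust choice, consistent with range-based transposition
at test time; rhythmic banks additionally require identical duration-class
sequences — and predicts a score for each item under both trial-type
coefficient sets. Published sets (`difficulty_model()`): arhythmic
intercept 0.74 with N −0.01, step-contour −0.32, tonalness +0.13, log
frequency +0.02; rhythmic intercept 0.37 with N −0.01, step-contour −0.50,
log frequency −0.02, duration entropy −0.26, interval entropy −0.19; plus a
combined set with a rhythmic indicator and its duration-entropy
interaction. Predictions are clipped to [0, 1]; lower predicted score =
harder item.

## Study-level modelling

`fit_trial_model()` fits the three published explanatory item response
specifications as linear mixed models (REML, lme4) with participant random
intercepts; only first attempts are modelled by default, matching the
empirical filtering of multi-attempt data. The random intercepts are the
ability scores. Variance is decomposed as Nakagawa–Schielzeth
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)$ and
$R^2_c = (\sigma^2_f + \sigma^2_r) / (\sigma^2_f + \sigma^2_r + \sigma^2_e)$,
with $\sigma^2_f$ the variance of the fixed-effect linear predictor.
Singular fits are reported, not masked — a zero random-intercept variance
is itself informative (it is the expected outcome when participant labels
carry no signal).

Composite scores use Horn parallel analysis (components retained while the
observed correlation eigenvalue exceeds the 95th percentile of eigenvalues
from standard-normal data of the same shape, stopping at the first
failure) followed by PCA with varimax rotation and iterative removal of
variables whose communality falls below a threshold (0.75 for the
long-note battery, 0.30 for the melodic-accuracy battery). Component
scores use the regression method (weights $R^{-1}\Lambda$); the scoring
method behind published composite extraction is not stated, and regression
scores are the common default. Rotation leaves the reproduced correlation
structure $\Lambda\Lambda'$ invariant, which is the invariant the tests
assert.

## What the simulators emulate — and what they do not

* `simulate_recall()` — per-note Gaussian pitch error (cents), note
  deletions, spurious neighbour insertions (±3 semitones), lognormal
  duration jitter. Onsets are rebuilt sequentially from the jittered
  durations (the singer keeps their own time).
* `simulate_long_note()` — cents deviation built as linear drift, an
  exponential onset scoop $-d\,e^{-t/\tau}$, sinusoidal vibrato and i.i.d.
  frame noise, converted to Hz around the target. Defaults follow the test
  protocol: 5 s tones; 100 frames/s is the simulator's frame rate, the
  order of a tracker's hop size.
* `simulate_study()` — abilities $\sim N(0, \sigma_a)$, expected outcome =
  feature linear predictor + ability, clipped to [0, 1], observed outcome
  with truncated-normal noise inside [0, 1]. Truncated-normal (rather than
  beta) noise keeps the generating model inside the linear-model family the
  analysis assumes, so recovery checks test estimation rather than link
  misspecification. When a coefficient set with a low intercept (the
  rhythmic set) is combined with wide feature ranges, the clip at 0 binds
  for hard items and attenuates fitted coefficients; recovery runs
  therefore draw item features in ranges that keep the expected outcome
  interior, because a boundary-clipped response is no longer generated by
  the model being fitted.
* `simulate_longnote_battery()` — per-participant values of the six
  retained long-note measures from three independent latent processes
  (volatility, accuracy, scoop) with block loadings mirroring the empirical
  three-component solution, unit indicator variances, and the changepoint
  count cross-loading on volatility and scoop. The composite pipeline is
  validated against this generator at the measure level: generating
  hundreds of audio-level tracks per participant would test the
  track simulator's incidental correlations, not the composite machinery.

Every stochastic operation is a pure function of its inputs and seed, and
restores the global RNG state.

What passing tests on these simulators do **not** show: robustness to real
transcription artifacts (octave errors beyond what the median smoother and
median-based range estimator absorb, spurious note segmentations, voicing
gaps correlated with pitch), systematic key-shifted recalls (explicitly not
modelled), non-Gaussian per-singer error distributions, or any property of
the audio front end itself (no audio decoding or f0 estimation is
implemented — delegated to the external tracker).

## Triage

`compute_snr()` implements $20\log_{10}(\mathrm{RMS}_s/\mathrm{RMS}_n)$
over the full recordings (no trimming window is applied, none being
specified for the production system) with the default 14 dB gate below
which pYIN-style transcription degrades substantially; a 0 dB profile
reproduces the earlier, laxer screening. A silent noise recording yields an
*undefined* SNR, distinct from a failure. Vocal range bounds are rounded
medians of voiced-frame MIDI (median, not mean, for octave-error
robustness); stimuli are transposed by the integer shift matching the
melody's mean pitch to the range mean, rounding half away from zero so up-
and down-shifts are treated symmetrically. At a residual of exactly half a
semitone this rounding alternates between two adjacent shifts (a ±0.5
residual rounds away from zero), so re-transposition is idempotent only
away from that boundary; both candidate shifts are equally good there.

## Problem sizes and numerical tolerances

The test and acceptance workloads are sized for a single CPU: the
edit-distance oracle sweep enumerates all ~1.2M pairs of length ≤ 6 over a
3-symbol alphabet against an independent implementation (the naive
recursive oracle, being exponential, is run exhaustively at length ≤ 3 and
sampled above); similarity property suites use 1,000 random melody pairs;
Krumhansl oracle checks 500 melodies; noise calibration uses 500 replicate
tracks (folded-normal mean within 5%); recovery studies use 100–200
simulated participants × 20 items. Mixed-model convergence is left to
lme4's defaults; PELT penalties and the 14 dB/0.75/0.30 thresholds are the
protocol constants above and are exposed through `saa_config()`.

## Known limitations

* Implied harmony uses fixed-length time windows, not metrical structure;
  window boundaries interact with note onsets, so `harmcore` between
  melodies of very different lengths is coarser than the other components.
* The accuracy family's positional alignment penalizes insertions early in
  a recall more than a musician would judge fair; that is by design (the
  similarity family handles alignment) but worth remembering when
  interpreting single measures.
* Difficulty predictions are linear and clipped; for extreme feature
  combinations the published coefficient sets predict at the boundary,
  where ordering among very hard items is not meaningful.
* The MIDI reader targets monophonic corpus files (format 0/1, one tempo
  after the first note, overlapping notes truncated at the next onset); it
  is not a general SMF implementation.
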