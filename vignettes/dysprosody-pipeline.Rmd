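---
title: "An automated dysprosody assessment pipeline: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An automated dysprosody assessment pipeline: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(prosodia)
```

`prosodia` turns a raw read-speech recording into an ordinal dysprosody
severity assessment. This vignette explains the models each stage
implements, the parameters that matter, the places where the design was
genuinely open and how we resolved them, and what the synthetic-data tests
do and do not establish about real clinical recordings.

## Utterance detection

Recordings are segmented into utterance-like vocal-activity spans before
any prosodic analysis. The built-in detector computes frame RMS in dB re
digital full scale (25 ms window, 10 ms hop) and thresholds it at
`max(noise_floor + margin_db, floor_db)`, where the noise floor is the 10th
percentile of the frame-dB distribution. Defaults: `margin_db = 12`,
`floor_db = -55` (the absolute floor keeps the threshold sane on digitally
clean recordings whose noise floor is essentially −∞), `max_gap_s = 0.3`
(gaps shorter than a typical inter-word pause are bridged),
`min_dur_s = 0.25` (sub-word blips are dropped), `pad_s = 0.05`. All are
config keys. The detector's frame-level resolution biases boundaries by up
to half an analysis window (12.5 ms); tests therefore locate boundaries to
±20 ms around the padded construction.

Neural overlap-aware detectors segment conversational recordings better
than energy thresholds; `register_external_vad()` accepts any callable
returning ordered, non-overlapping spans so such a detector can stand in
without the package shipping model weights.

## Two-pass f0 tracking

Fundamental frequency is estimated by normalized autocorrelation on 40 ms
windows with the 10 ms hop used throughout the package, with parabolic
interpolation of the peak lag and a voicing decision at a normalized peak
of 0.45 (config key). The estimator family was an open choice — the
two-pass scheme is defined independently of it — and autocorrelation was
chosen as the canonical front-end of intonation-stylization practice; any
tracker meeting the synthetic-fixture tolerances (2% on a planted constant,
3% on a planted glide) would be conformant.

Pass one searches 60–750 Hz. The first quartile q₁ of the voiced pass-one
values — computed after a width-5 median filter that suppresses octave
jumps, with the linear-interpolation quantile convention so q₁ is exactly
reproducible — defines the pass-two search space [0.75·q₁, q₁·2^1.5]. The
narrowed space removes octave errors without any age- or sex-specific
configuration; a property test asserts the two-pass track is never less
accurate than the single pass on clean synthetic voice.

## Momel stylization

The macro-prosodic contour is modelled as a C¹ piecewise-quadratic spline
through Momel target points (MTPs), with knots at the midpoints between
consecutive MTPs. Anchor slopes follow the parabola through each anchor
triple (Bessel construction); with two anchors the spline degenerates to
the connecting line, and an independent linear-system construction of each
segment serves as the test oracle.

Deriving MTPs from a track proceeds in three steps (window sizes follow the
canonical published implementation; the source method leaves the internals
open): (1) a local quadratic regression of voiced f0 in a 300 ms sliding
window, with one refit after excluding frames deviating more than 5% from
the fit; the candidate target is the parabola vertex when it falls inside
the window — vertices of windows straddling a tonal turning point cluster
on that turning point — and the fitted window-center value otherwise;
(2) candidates are partitioned over 200 ms reduction windows and averaged,
vertex candidates taking precedence when a window holds at least three;
(3) the first and last local fits are kept as dedicated boundary targets
and targets closer than a quarter reduction window are merged. The 200 ms
reduction window yields roughly five MTPs per second; planted-anchor
fixtures (quadratic splines plus 1% multiplicative noise) are recovered to
50 ms and 5%. One caveat discovered during design: an anchor of the
generating spline is only recoverable when it is (close to) a turning point
of the curve — strongly asymmetric valleys place the curve minimum tens of
milliseconds past the anchor, and no curve-driven stylizer can undo that.

## INTSINT annotation

Each MTP is coded with one of eight symbols under a speaker model with key
(Hz) and span (octaves): absolute levels T = key·2^(span/2), M = key,
B = key·2^(−span/2); relative levels defined on the log scale from the
previous target's coded value — S repeats it, H/L sit at the log midpoint
toward T/B, U/D a quarter of the log distance toward T/B. All errors are
measured in log frequency (octave-scaled), consistent with the levels being
defined there; Hz-scale error would over-weight high-frequency targets.

Key and span are found by grid search: span 0.5–2.5 octaves in 0.05 steps;
key on a ±0.5-octave grid around the mean MTP f0 in 50 steps (51 points
including the center), traversed outward from the center with
strict-improvement updates. The outward traversal implements a stepwise
search originating at the mean f0 and resolves exact ties toward the
central key — a constant contour is thus coded `M S S …` at its own mean
rather than `T T T …` at a key half a span lower, which fits the same data
exactly. Labels are assigned left to right greedily (the first MTP
restricted to the absolute labels {M, T, B}, the canonical convention),
each label minimizing the log-frequency error given the previously coded
value; an exhaustive search over the full label-sequence space on small
contours confirms the greedy assignment attains the same optimum on
coding-model-generated contours. A dynamic-programming assignment would be
an exact alternative for adversarial contours; it is noted as an extension.

## Acoustic measurements

Each MTP is measured in a 30 ms Hann window centered on its time (the
window length around a target is not pinned down by the source method; 30 ms
covers 3–6 glottal cycles in the 100–220 Hz range and is a config key).
Measures and conventions:

* **Intensity**: 10·log₁₀ mean squared amplitude re digital full scale
  (a full-scale sine is −3.01 dB). No SPL calibration is attempted — WAV
  files carry none — so only intensity *differences* are meaningful.
* **SER**: 10·log₁₀ of the 0–1 kHz over 1–5 kHz band power ratio on the
  one-sided, Parseval-scaled power spectrum; degenerate bands cap at
  ±60 dB with a flag.
* **Harmonic levels** L₁–L₃: spectral peaks nearest k·f0 within ±f0/4,
  parabolically interpolated. The formant-corrected versions subtract each
  nearby formant's resonator gain (pole radius `exp(−πB/fs)`) normalized to
  its DC gain; bandwidths come from the two-branch Hawks–Miller polynomial
  with its f0-dependent scaling, formant frequencies from autocorrelation
  LPC of order `2 + rate/1000` (pre-emphasis 0.97). Because that order
  over-parameterizes few-resonance spectra, root candidates are filtered
  through the peaks of the LPC envelope, one formant per peak.
* **C₁**: 26 triangular Mel filters spanning 0 to Nyquist, each normalized
  to unit weight so a flat spectrum yields equal filterbank energies (and
  C₁ ≈ 0 — without the normalization the growing filter widths alone would
  produce a spurious tilt term), log energies, orthonormal DCT-II,
  coefficient 1. Gain lands entirely in coefficient 0, so C₁ is
  amplitude-invariant; steeper negative tilt gives larger C₁.
* **Spectral polynomial fits**: least squares on the log-magnitude
  spectrum over 0–5 kHz with frequency in kHz (keeping coefficients
  O(1)–O(10)); order 1 keeps the slope (SLF), order 6 keeps the six
  non-constant coefficients (SLF6D) — the constant is gain, already
  captured by intensity.

## The 205-predictor battery

Per utterance the battery contains timing (15), f0 (16), intensity (16)
and spectral-tilt (158) predictors; level quantities are summarized at the
MTPs and as MTP-to-MTP changes by six statistics (min, max, mean, sample
SD, CV = SD/mean with an undefined marker at zero mean, IQR with
linear-interpolation quantiles). Two slots in the source battery are
ambiguous and were reconstructed, preserving the 205 total: the utterance
duration appears twice in the timing domain (both slots are emitted,
`utt_duration_s` and `utt_duration2_s`; the correlation screen removes the
duplicate before modelling), and the intensity domain repeats the "f0 key"
row, reconstructed here as the utterance mean intensity (`int_mean_db`).
The two utterance-level long-term-average-spectrum (LTAS) slots are the SER
of the utterance-averaged power spectrum (`ser_ltas_db`) and the RMS
deviation of the per-MTP SER changes about that value (`dser_sd_ltas_db`),
which reconciles the per-row counts of seven with the LTAS naming of the
importance rankings. Utterances with fewer than two MTPs are excluded with
a reason code rather than imputed — their change features are undefined.
The name list is frozen and checksummed; trained model bundles refuse
feature tables with a different checksum.

## Severity modelling

Predictors with |Spearman ρ| > 0.9 form a graph whose connected components
are each represented by the member best correlated with the outcome.
Hyperparameters are tuned by stratified 10-fold cross-validation on mean
log loss over maximin Latin-hypercube candidates drawn within the
documented ranges (log scale for the SVM cost and the elastic-net mix;
1,000 candidates by default, far fewer in tests). The maximin LHS stands in
for a maximum-entropy/variogram space-filling design — both are
space-filling families and LHS is reproducible from a seed. Four learners
are implemented: polynomial SVM (degree 3), a penalized proportional-odds
model with an L1/L2 mix (the L1 term smoothed as √(β²+ε) so BFGS applies;
no installed package fits an ordinal likelihood with an elastic-net
penalty), random forest, and kernel-weighted kNN with the nine standard
kernels and a tunable Minkowski exponent in [1, 2] (the distance parameter
had no printed range; a config key). "Averaging the ten fold models" is
interpreted as probability averaging — parameter averaging is undefined
across kNN and forests. The stacked ensemble learns non-negative weights
summing to one over the base models by minimizing log loss on out-of-fold
predictions; a free multinomial meta-learner on probabilities cannot
enforce the non-negativity the weighting is meant to have.

FIRM importances are estimated partial-dependence style: each predictor is
clamped to the medians of its ten quantile bins, and the importance is the
population SD of the model's mean class probabilities across bins, averaged
over the three classes (exact FIRM needs the true feature distribution; the
reference sample stands in for it, and the scored output — averaged class
probabilities — was an open choice). On a linear scorer this reduces to a
quantity proportional to |wⱼ|·SD(xⱼ), which the tests verify, including
invariance to rescaling a predictor while counter-scaling its coefficient.

An ordinal baseline using only utterance-wide f0 variability
(`baseline_f0sd_model()`) provides the comparison against the literature's
predominant single-proxy approach.

## The synthetic corpus: what it emulates and what it does not

No clinical recordings ship with the package; a seeded generator provides
the study conditions. Each utterance is a sawtooth source following the
quadratic-spline interpolation of 4–9 planted targets, shaped by a
frequency-domain tilt filter (dB/octave re 500 Hz; applied per inter-target
segment with 10 ms crossfades when tilt varies within the utterance — a
single recursive pole cannot realize arbitrary slopes, so the shaping is
done exactly in the frequency domain), a 500/1500/2500 Hz resonator
cascade, a piecewise-linear intensity envelope, and surrounding silence.

Corpus structure: severity labels are assigned per speaker (ratings are per
recording, and holding out whole speakers exercises the grouped split);
speaker keys are uniform on 100–220 Hz. Log-f0 targets follow a stationary
AR(1) walk around the key whose autocorrelation φ encodes severity: the
step SD is `base · multiplier` with φ = 1 − multiplier², while the
stationary spread is the same for every class. This is the critical design
property: utterance-wide f0 variability carries (almost) no class signal by
construction, only the local change dynamics do — so the f0-SD-only
baseline is beatable for the right reason, mirroring the clinical finding
the pipeline is built around. Severity multiplies down the f0 step SD
(1 / 0.45 / 0.18 of a 2.5-semitone base), the per-target tilt dynamics
(1 / 0.5 / 0.2 of 4 dB/oct) and the intensity range (1 / 0.5 / 0.25 of
18 dB) — strong monopitch/monoloudness effects at the top of the clinically
described range, with 10% log-normal speaker-level jitter. The end-to-end
test (20 speakers × 5 utterances, seeded) requires a tuned random forest to
reach macro balanced accuracy ≥ 0.80 on held-out speakers and to strictly
beat the f0-SD baseline; the validity link between synthesis and analysis
is the Spearman ρ ≥ 0.7 between the extracted `mtp_df0_sd` feature and the
planted per-utterance step SD.

What passing these tests shows: the pipeline recovers planted prosodic
structure through the full audio path, and the model layer turns it into
severity predictions with honest grouped evaluation. What it does not show:
robustness to consonantal segments, creak and diplophonia, background
noise, channel variation, or the actual effect sizes of clinical speech —
the synthetic effects are planted, not estimated from patients. Reported
clinical-scale performance can only be checked against the re-entered
reference count matrices, which the metric layer reproduces cell for cell.

## Evaluation conventions

Macro one-vs-rest averaging (unweighted over the three classes) reproduces
every printed cell of the reference tables at two decimals; this validates
the convention choice. A class never predicted leaves the macro PPV
undefined (reported `NA`, printed "–") and contributes an F score of 0.
Display rounding is half-away-from-zero with an epsilon guard so exact
halves like 0.675 round to 0.68 regardless of binary representation.
Consensus ratings take the rater mode with ties broken toward the more
severe category (the tie rule was unstated; breaking toward severity is the
clinically conservative choice). Cohen's kappa uses marginal-product
expected agreement, defined as 1 when both raters are constant and equal.
ROC curves are one-vs-rest threshold sweeps with trapezoidal areas.

## Problem sizes and numerical choices

The shipped tests run the full audio pipeline on a 100-utterance corpus at
16 kHz and tune learners with 3–20 candidates over 5–10 folds — sizes
chosen so the whole suite exercises every path in a few minutes while the
statistical checks (balanced accuracy, correlation links, brute-force
metric oracles at n = 100 matrices) remain sharp. Defaults for production
use are larger (1,000 tuning candidates) and all sizes are config keys.
Degenerate inputs are handled explicitly: silent frames floor at −120 dB
with flags, unvoiced utterances and sub-2-MTP stylizations are skipped with
reason codes, singular local fits fall back to lower polynomial degree,
and probability rows are renormalized onto the simplex before scoring.
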