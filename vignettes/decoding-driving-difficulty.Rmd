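---
title: "Decoding driving difficulty from fNIRS hemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding driving difficulty from fNIRS hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nirsdecode)
```

## The scientific problem

A driver's cognitive state reflects at least two interacting demands:
*working memory load* (WML) and *visuospatial driving difficulty*. In the
dual-task paradigm this package models, WML is manipulated with an n-back
speed-regulation task (drive at the speed posted *n* signs ago, n = 0-4) and
difficulty by alternating normal highway with narrowed construction-site
sections, in 3-minute blocks. Cortical hemodynamics are recorded with
functional near-infrared spectroscopy (fNIRS): two-wavelength optical
intensities at 1.955 Hz over 78 emitter-detector channels (~3.5 cm
separation), converted to oxy-/deoxyhemoglobin concentration changes. The
central question is whether driving difficulty can be decoded from the
deoxyhemoglobin (HbR) signal, and whether the difficulty-related activation
pattern *changes with WML* — a brain-level task interaction. The empirical
signature of such an interaction is that per-WML-level classifiers decode
difficulty well while a single classifier pooled over WML levels drops to
chance.

Because no raw recordings are publicly available, the package pairs the
analysis pipeline with a forward simulator whose ground truth is known, so
every stage is testable and the headline phenomenon can be reproduced
end to end.

## The forward model

**Design.** `generate_design()` builds the session: each (level, difficulty)
cell driven twice, difficulty alternating with every change of n-back level,
level order pseudorandom with no immediate repetition within a session half,
and the second half replaying the first half in reverse (a palindrome around
the midpoint break). A strict mirror forces the level of the last pre-break
block to recur right after the break; the break itself separates that pair.
Exact per-level class balance additionally requires each level to occupy one
odd and one even position in the first half, which the sampler enforces by
rejection; this is also why `reps_per_cell` must be even. Speed signs are
placed every 20 s with uniform ±25% jitter; posted speeds walk a
60-140 km/h grid in ±20 steps so consecutive signs always differ.

**Hemodynamics.** Condition boxcars are convolved with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6), normalized so a
sustained boxcar response equals its amplitude; amplitudes therefore read as
sustained concentration changes in mmol/L. HbR is coupled to HbO as
ΔHbR = −⅓ ΔHbO by default. The WML factor drives one fixed spatial pattern
scaled linearly with level; the difficulty factor drives a pattern that
`interaction_strength` morphs from level-independent (0) to fully
level-specific (1).

**The interaction dial.** At full interaction the per-level difficulty
patterns are the vertices of a regular simplex over disjoint channel groups:
equal norms, pairwise correlation −1/4, and *exact zero sum*. The zero-sum
property is what makes the combined model fail: for any weight vector the
per-level margins sum to zero, so no single linear readout can separate
construction from non-construction at every level simultaneously, while each
level remains cleanly separable on its own. (Literally orthogonal
level-specific patterns would *not* produce this: orthogonal patterns admit
the common readout `w = Σ p_l` with positive margin at every level, and the
pooled model would succeed.)

**Noise.** Cardiac (~1.1 Hz), respiratory (~0.3 Hz) and Mayer-wave
(~0.1 Hz) sinusoids with per-channel random phases; white instrumental
noise; and motion artifacts — Poisson-timed spikes with fast decay, each
followed by a slowly decaying baseline shift, shared across channels through
a per-channel gain vector (a near-rank-one structure, which is the premise
of first-PC deletion). The cardiac frequency exceeds the 0.98 Hz Nyquist
rate and is evaluated directly at the sample times, so it aliases to
0.855 Hz as in a real recording. Motion shifts decay (default 20-25 s) rather
than accumulating as a random walk: bounded motion variance is what keeps
the session stationary enough for correlation-based PCA, and fast motion
dynamics prevent chance temporal correlation between the motion time course
and the condition boxcars inside a training fold — when motion is slow, the
first principal component mixes motion with signal and deleting it destroys
the signal.

**Optics.** The modified Beer-Lambert law maps concentration changes to
optical-density changes, ΔA(λ) = (ε_HbO(λ)ΔHbO + ε_HbR(λ)ΔHbR)·d·DPF(λ),
with the Gratzer extinction coefficients at 760/850 nm, DPF 7.25/6.38, and
d the emitter-detector distance in cm; intensities are I₀·10^(−ΔA).
`mbll_invert()` solves the same 2×2 system, making the round trip exact to
machine precision when the simulator's baseline is used as the OD reference.
A real recording's baseline is unknown, so the analysis default references
the temporal mean intensity; recovered concentration changes are then exact
up to a constant per-channel offset, which is irrelevant after filtering and
standardization.

## Preprocessing

1. **Channel QC**: coefficient of variation (100·sd/mean) per channel and
   wavelength on the *unfiltered* raw intensities; a channel is excluded if
   either wavelength exceeds 20%. CV is computed on intensities (not OD),
   and per wavelength, with exclusion if either fails.
2. **Low-pass filtering**: a 101-tap least-squares linear-phase FIR with
   0.1 Hz cutoff (transition to 0.13 Hz), normalized to exact unit DC gain,
   applied with zero phase. The forward-backward application is implemented
   as one convolution with the kernel's autocorrelation plus reflection
   padding, so edges are handled deterministically; the realized attenuation
   is the squared magnitude response.
3. **MBLL inversion** to HbR/HbO (mmol/L); the decoding substrate is HbR.
4. **Behavioral segment exclusion**: a sign-to-sign segment is invalid when
   less than 90% of its 50 Hz samples are within ±5 km/h of the n-back
   target (the 90% boundary passes); all fNIRS samples in invalid segments
   are masked. The same scorer backs the behavioral error-rate tables, so
   both modules share one source of truth.
5. **PCA denoising** is *not* applied globally: it is fitted inside training
   folds by the decoder, and per condition by the univariate map analysis.
   Channels are standardized on the training data (correlation-matrix PCA,
   so the 0.7 eigenvalue threshold matches the Kaiser/Jolliffe convention);
   the first component is always deleted (motion), and only remaining
   components with eigenvalues above 0.7 are kept for reconstruction.
   Covariance-based PCA is available behind a flag. If a training fold's
   spectrum leaves no retainable component, the fold proceeds undenoised
   with a warning (a direct call to `pca_denoise_fit()` errors instead,
   instructing a lower threshold); skipping such folds outright starved the
   penalty selection and produced intercept-only models that anti-predict
   class-blocked test folds.

## Decoding

Difficulty is decoded from multichannel HbR samples with L2-penalized
logistic regression, written in-package as a damped Newton solver on the
penalized mean binomial deviance (intercept unpenalized, gradient norm
< 1e-6). Nested cross-validation: five contiguous outer folds over the valid
samples in temporal order (remainders to the earliest folds); within each
outer training set, five inner folds select the penalty from 50 log-spaced
values in [1e-4, 1e4] by mean out-of-sample accuracy under the
one-standard-error rule: the largest penalty whose inner accuracy is within
one standard error of the best is chosen, so ties — exact or statistical —
go to the stronger penalty. (A plain argmax over so fine a grid selects
essentially at random among penalties whose accuracies differ only by
validation noise.) PCA denoising and per-channel z-scoring are fitted on the
respective training portion only and applied to held-out data with training
statistics — no leakage. Samples with fitted probability ≥ 0.5 are assigned
to construction (the boundary is inclusive). Accuracy is
100·(TPc + TPnc)/(TPc + TPnc + FPc + FPnc) and the construction F1 score is
2·TPc/(2·TPc + FPc + FPnc).

Model variants: one decoder per WML level (`mode = "per_level"`), one pooled
decoder (`"combined"`), and all 45 pairwise decoders over the ten
(level × difficulty) conditions (`pairwise_dissimilarity()`), summarized by
the mean within-level and adjacent-level accuracies
(`within_adjacent_summary()`).

Blocked cross-validation on a balanced design has a known anti-learning
property: any chance association between labels and slow structure inside
the training folds reverses in the held-out fold, biasing null-effect
accuracies slightly *below* 50%. The pooled model at full interaction
inherits this (simulated mean ≈ 46%, published mean 46.8%), which is why
"chance level" for the combined model is a band around 50, not 50 exactly.

## Univariate predictivity maps

Per channel and WML level, a single-feature logistic regression of
difficulty on the (per-level PCA-denoised) HbR series is scored with Tjur's
coefficient of discrimination: the difference between the mean fitted
probabilities of the two classes, 0 = no predictivity, 1 = perfect.
Participant maps are combined into a group map by weighting each participant
with their multivariate decoding accuracy and normalizing by the summed
weights (a convex combination; channels a participant lacks are omitted from
that channel's sums). Negative Tjur values from pathological fits are
clamped to 0 only in the report's display column. Tjur R² saturates near 1
when a channel separates the classes with a wide margin, which erases rank
information among strong channels — pattern-rank recovery is therefore
checked at moderate SNR, while attenuation profiles (map maxima across
levels) are checked at high SNR where saturation is harmless.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `cv_threshold` | 20 | % | channel rejection bound on CV |
| `cutoff` | 0.1 | Hz | FIR low-pass passband edge |
| `n_taps` | 101 | — | FIR length (~51 s at 1.955 Hz) |
| `eigen_threshold` | 0.7 | — | PCA retention bound (correlation scale) |
| `tolerance` | 5 | km/h | speed-keeping tolerance |
| `criterion` | 0.9 | — | minimum in-tolerance fraction per segment |
| `k_outer`, `k_inner` | 5, 5 | — | CV fold counts |
| `lambda_grid` | 50 pts, 1e-4-1e4 | — | ridge penalty grid |
| `hbr_to_hbo_ratio` | −1/3 | — | chromophore coupling |
| `interaction_strength` | 0-1 | — | difficulty-by-WML pattern morphing |

## Simulation regimes and problem sizes

Two presets (`study_presets()`): `"default"` is a moderate-SNR regime;
`"high"` strengthens the difficulty response (sustained HbO amplitude
1.2e-3 mmol/L across the pattern) and weakens physiological/instrumental
noise while keeping motion large and almost perfectly rank-one. The high
preset is calibrated so that the generator's own contracts hold throughout
nested cross-validation: the first principal component is motion in every
training fold (so deleting it is safe), and the difficulty-signal
eigenvalues clear the 0.7 retention threshold with margin (~1-2). The
published study gives no amplitude or SNR figures, so these presets are
calibrated to reproduce the qualitative accuracy ordering, not absolute
values.

Analyses in the test suite and the reproduction script use 16-channel
sessions with 90-s blocks (≈704 fNIRS samples per per-level model, ≈3520
for the combined model) and cohorts of 6-10 simulated participants; the
generator's defaults remain the full study conditions (78 channels, 180-s
blocks, ~60-minute session). Behavioral miss probabilities and steering
reversal rates default to the published group-level per-cell rates, which
makes roughly 8% of segments fail the speed criterion.

## What the simulator does not emulate

Superficial/systemic physiology shared between scalp and cortex (no
short-separation channels), photon transport (a single effective path per
channel), realistic vehicle dynamics (the driver is a first-order lag with
per-segment misses), non-stationary electrode-contact drift, and
participant-level anatomical variability. Passing tests on synthetic data
therefore demonstrate the *pipeline's* correctness and the internal
consistency of the interaction logic — not that real fNIRS recordings carry
the simulated effect sizes.

## Numerical choices and degenerate inputs

* OD reference: temporal mean intensity (a real recording's true baseline is
  unknowable); the simulator's stored baseline is used only to verify
  exactness of the round trip.
* DPF values are assigned to wavelengths in listed order (7.25 → 760 nm,
  6.38 → 850 nm); DPF is physically a per-wavelength quantity.
* Filter edges: reflection padding; the first/last half-window samples are
  kept, not trimmed; masked samples are excluded from fitting, never
  interpolated.
* Inclusive decision boundary (p ≥ 0.5 → construction) and inclusive
  segment criterion (exactly 90% passes).
* Zero steering samples continue the previous sign (no double-counted
  crossings); the hysteresis band defaults to 0.
* Penalty selection uses the one-standard-error rule (statistical ties go
  to the stronger penalty); degenerate (single-class) inner folds are
  skipped with a warning; if all inner folds degenerate, the strongest
  penalty is used.
* Permutation-null checks use the 0-back cell, whose behavioral exclusion
  rates are symmetric between difficulties: the null then centers near 50%
  rather than at the majority-class rate of an unbalanced cell.
* The combined model pools all ten cells without reweighting, and fold
  blocks are contiguous in the concatenated valid-sample order.

## Known limitations

The anti-learning bias of blocked cross-validation makes single-session
combined-model accuracies scatter widely (sd ≈ 5 percentage points across
simulated participants); cohort means are the stable quantity. Tjur-based
maps lose rank information at extreme SNR. The univariate analysis applies
PCA per condition while the multivariate analysis applies it per training
fold; both entry points are exposed (`predictivity_map()` vs.
`nested_cv_decode()`), and the package does not attempt to reconcile this
difference — it mirrors the two analyses as reported.
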