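---
title: "Wavelet-packet features and channel selection for high-density sEMG: methods"
author: "wpemg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-packet features and channel selection for high-density sEMG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own methods: the signal
model and the assumptions behind each stage, the parameters that matter
and why their defaults are what they are, what the synthetic generator
does and does not emulate, and the numerical and design decisions that
were genuinely open.

## The problem and the pipeline

A high-density sEMG session consists of C movement classes, each
performed in R contraction repetitions, recorded on L bipolar channels
at sampling rate f~s~. The classification sample is not a trial but an
*analysis window*: a fixed-length multichannel slice of the active
(contraction) part of a trial. The pipeline is

1. activity segmentation (stored intervals or a double-threshold
   detector),
2. sliding-window segmentation (256 ms, 75% overlap),
3. per-channel, per-window features: wavelet-packet subspace
   log-energies (or the Hudgins time-domain set),
4. per-channel best-basis selection by the scalar separability index,
5. concatenation across channels, ULDA reduction, LDC classification,
6. repetition-wise cross-validation, and — around all of this —
7. channel selection (FCSI ranking, SFS, or combined FCSI + SFS).

The central modelling assumptions: windows from the same class are
identically distributed within a repetition; the within-class feature
distribution is reasonably summarized by means and variances (both the
separability index and the linear classifier use only first and second
moments); and repetitions are the natural exchangeable unit, so folds
and inner validation splits are always defined by repetition, never by
window.

## Feature extraction

**Wavelet packet transform.** Every channel of every window is expanded
into the complete binary tree of depth J = 4: node (j, k) covers the
k-th frequency subband at scale j, and splitting both approximation and
detail at every level gives 2 + 4 + 8 + 16 = 30 subspaces. The analysis
wavelet is the order-5 symmlet, a standard choice for sEMG
time-frequency analysis; `haar` and `db4` are available for
sensitivity checks. The per-subspace feature is
`log(sum(coefficients^2) + epsilon)`.

Numerical choices:

* **Boundary handling** defaults to periodization, under which the
  filter bank is exactly orthonormal, so the 16 leaf energies sum to the
  window energy to machine precision (the test suite asserts 1e-8
  relative). Symmetric reflection is available but does not conserve
  energy exactly. Periodization requires the window length in samples
  to be a multiple of 2^J; the default 256 ms at 2 kHz gives 512 = 32 ×
  16 samples. Window and step lengths are rounded half-away-from-zero,
  so the implied 512/128 sample values are reproduced at any sampling
  rate without platform-dependent banker's rounding.
* **epsilon = 1e-12** guards the logarithm on silent channels; a
  degenerate all-zero window yields the well-defined feature vector
  log(1e-12) everywhere.
* **Natural log, natural (j, k) node order.** The log base is a free
  affine rescaling of every feature; the separability index is invariant
  under affine maps, so the choice cannot affect selection. Node order
  only fixes column bookkeeping — selection is order-agnostic.

**Time-domain set.** MAV, zero crossings, slope-sign changes and
waveform length, with amplitude deadzones for ZC and SSC defaulting to
0 (no deadzone); they are exposed because real recordings with baseline
noise benefit from a small deadzone, but the synthetic conditions do
not need one.

**Activity detection.** Real protocols mark contraction onset/offset
with dedicated detectors; the package ships a deliberately simple,
deterministic double-threshold detector on the moving average (50 ms) of
the rectified channel-summed signal, with baseline statistics from the
first 50 ms, onset at baseline + 3 SD, offset at baseline + 1 SD, and a
500 ms minimum segment. It is plumbing, not a contribution: datasets can
(and the synthetic generator does) carry ground-truth active intervals
in the manifest, bypassing it. Intervals are 0-based half-open, which
composes cleanly with the window arithmetic.

## Separability index and best-basis selection

For class-grouped scalar features the index sums, over all unordered
class pairs, the squared mean difference divided by the sum of the two
class variances. Two literal readings were fixed deliberately:

* **Population variances (1/N).** The defining formula normalizes by
  N~c~, not N~c~ − 1. For equal class sizes the distinction rescales
  every pairwise term identically and cannot change any ranking; the
  literal form is kept.
* **The pair sum runs over all C classes.** The bound of the double sum
  is read as the class count of the data at hand.

Degenerate inputs: a class pair with zero pooled variance but separated
means is perfect separability — the index returns +Inf (with a warning),
which sorts first in rankings; zero variance with equal means
contributes 0. Ties in rankings are broken by natural (j, k) order, and
in channel selection by lowest channel index, making every selection
deterministic.

Best-basis selection keeps the top n = 12 subspaces per channel,
independently per channel. The default follows the standard trade-off
between discriminative coverage and classifier dimensionality; the
sensitivity sweep over n is a one-line loop over
`selectBestBases(fm, n)`. When a training mask is supplied, scores are
computed from training rows only — the leakage tests assert that
corrupting or relabelling held-out rows cannot move the selection.

## ULDA and the linear discriminant classifier

ULDA finds a projection maximizing between-class scatter against total
scatter under the constraint that transformed training features are
mutually uncorrelated (identity total scatter). It is realized by
simultaneous diagonalization with two economy SVDs: an SVD of the
centered data whitens the total scatter in its range; the whitened
between-class structure's left singular vectors, truncated at rank ≤
C − 1, complete the projection. Rank decisions use the standard
`max(dim) * eps * max(singular value)` tolerance, and a ridge of
1e-6 × the mean spectrum stabilizes the whitening when the total scatter
is rank-deficient (which happens whenever 552 features meet fewer
windows, and in the channel-selection inner loops). Each projection
column's sign is fixed by making its largest-magnitude loading positive,
so fits are bit-reproducible.

The classifier models each class as a Gaussian with the pooled
within-class covariance (n − C normalizer) and assigns by the MAP rule,
which is linear in the features. Priors default to uniform — the design
is balanced by protocol (equal repetitions per class) and a held-out
repetition keeps that balance — with empirical priors as an option.
Optional shrinkage toward the scaled identity handles singular pooled
covariances; after ULDA the covariance is well-conditioned and the
default shrinkage is 0. Exact score ties go to the lowest class label,
and the brute-force Gaussian-MAP oracle test pins the decision rule
exactly.

Cross-validation fits everything — best-basis selection, ULDA, LDC — per
fold on the training repetitions only. Whether a single global ULDA
would be admissible is debatable; the per-fold reading is the
leakage-safe one and is enforced. Pooled accuracy is total correct over
total tested windows (not the mean of fold accuracies), which matters
when folds have unequal window counts.

## Channel selection

All three algorithms operate on the best-basis-reduced features of the
training repetitions; the highest repetition index is held out
throughout and only touched by the final evaluation.

* **FCSI ranking** scores each channel's 12-dimensional feature vector
  with the multivariate index (variance = sum of per-dimension
  population variances, numerator = squared Euclidean mean distance) and
  keeps the top m. It ignores inter-channel redundancy by construction.
* **SFS** greedily adds the channel maximizing inner-validation accuracy
  of the full ULDA + LDC pipeline on the candidate union. The inner
  split stays inside the training repetitions. The literal protocol is a
  single 3-train / 1-validate split; the default here rotates the
  validation repetition over the four training repetitions and averages,
  which reduces the variance of the greedy criterion at 4× the cost.
  `innerSplit = "single"` restores the literal protocol.
* **FCSI + SFS** replaces the accuracy criterion with the multivariate
  index of the concatenated features, so no classifier is trained during
  the search. When the concatenation exceeds `uldaDimThreshold = 40`
  dimensions, it is first reduced by ULDA and the index evaluated in the
  reduced space. The threshold was fixed at 40 once: with 12 features
  per channel it leaves unions of up to 3 channels unreduced (where the
  raw index is well-conditioned) and reduces beyond that, where
  accumulated dimensions would otherwise dilute the index. Both the
  threshold and whether reduction occurred are visible in the audit
  trail.

Every step of every method logs all candidate scores, so selections can
be audited after the fact.

### A known limitation of the FCSI criterion

The multivariate index sums per-dimension variances and contains no
covariance term. Consequence: if a channel is an exact duplicate of an
already selected one, the union scores exactly the single channel's
index (numerator and denominator both double pairwise), i.e. the
criterion treats redundancy as *neutral*, never harmful. One can show
that whenever the duplicated channel was the first pick, no
complementary channel can strictly outscore the duplicate under the
unreduced criterion (per class pair the comparison reduces to which
single channel scores higher), and empirically the ULDA-reduced variant
behaves the same. The test suite pins this behavior against exhaustive
evaluation of the step criterion, and contrasts it with accuracy-driven
SFS, which rejects the duplicate outright. In practice sEMG channels are
never exact duplicates and the greedy index still recovers complementary
informative channels reliably (see the recovery results below), but a
user selecting among highly correlated neighboring electrodes should
prefer SFS or inspect the audit trail.

## The synthetic generator

Each trial is 1 s rest, a 3 s contraction burst under a trapezoidal
envelope (200 ms rise/fall), and 1 s rest, at 2 kHz. A channel's burst
is white Gaussian noise band-pass filtered (4th-order Butterworth,
forward-backward, 20–500 Hz by default), normalized to unit SD and
scaled by a class gain; a white noise floor (SD 0.05 against burst
amplitude 1) is always present. This amplitude-modulated band-limited
Gaussian noise is the standard stationary surrogate for
interference-pattern sEMG; it is sufficient here because every algorithm
under test consumes window energies and amplitudes, not motor-unit
structure.

Class information lives only on the configured informative channels,
through a **factorial class code**: each class receives a k-digit
base-T code (k = number of informative channels,
T = ⌈C^(1/k)⌉), one digit per informative channel, permuted across
classes by the seed. Digit values map to amplitude gains spaced
geometrically up to `gainRatio = 3` between extremes (gain coding), to
class passbands of width 120 Hz placed across the EMG band (spectral
coding), or both (the default). The factorial structure makes the
informative channels complementary and none redundant — no proper subset
of them separates all classes — which is exactly the situation channel
selection exists for, and it prevents the greedy searches from
saturating before the last planted channel. With `coding = "none"` the
generator produces null data with no class effect anywhere.

What the generator does **not** emulate: motor-unit recruitment and
MUAP shapes, nonstationarity within a contraction, electrode-shift and
crosstalk structure (neighboring channels are independent given the
class), and any stroke-specific pathophysiology. Passing tests therefore
demonstrate algorithmic correctness and sensible behavior under the
assumed moment structure, not clinical performance on paretic muscle
recordings.

Fixtures: `tiny` (4 × 3 × 6, 2 informative; unit tests), `default`
(20 × 5 × 16, 3 informative; the standard validation condition), and
`fullscale` (20 × 5 × 46, 10 informative; mirrors a full high-density
bipolar session). The validation suite and the acceptance script run the
`default` condition — 4300 windows, 480 wavelet features before
selection — which keeps the complete 20-seed recovery study and all
cross-validated accuracies within a few minutes on one core.

## What the validation shows

With the default conditions: all three selection algorithms recover the
3 planted channels in their top-3 in 20/20 seeded sessions; pooled
cross-validated accuracy is at ceiling on the separable fixture, at
chance (≈ 1/20) on null data, and the wavelet features match or beat the
time-domain set on the spectral-coding fixture; 10 optimally selected
channels clearly beat an arbitrary predefined 10 (which by construction
misses one informative channel). These numbers are recomputed, not
stored, by `scripts/acceptance.R` and the acceptance tests.

## Degenerate inputs and edge behavior, collected

* Windows shorter than 2^J samples, unknown wavelets, non-positive
  thresholds, out-of-range channel pairs and subset sizes: validation
  errors naming the offending quantity.
* Segments shorter than one window are rejected by `segmentWindows`;
  `extractFeatures` skips such segments (trailing partial windows are
  dropped, never padded).
* A single class refuses to fit ULDA/LDC; classes with one sample refuse
  the pooled covariance.
* Singular pooled covariance without shrinkage raises an error that
  names the remedy.
* All algorithms are deterministic given their inputs; the generator is
  bit-reproducible from its seed and restores the caller's RNG state.
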