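---
title: "Attention monitoring from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention monitoring from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attneeg)
```

## Overview

`attneeg` estimates a five-level ordinal attention state (low, medium-low,
medium, medium-high, high; integer codes 0–4) from four-channel EEG
(TP9, AF7, AF8, TP10 — temporal and frontal sites commonly available on
consumer headsets) and feeds the estimate back into closed-loop
neurofeedback games. The pipeline is

1. epoching (default 1 s windows at 256 Hz),
2. five-level discrete wavelet decomposition per channel (db4),
3. SURE soft-threshold denoising of the detail coefficients,
4. per-subband reconstruction and mean-power features
   (4 channels × 5 bands = 20 features),
5. a bootstrap CART ensemble with majority voting ("improved random
   forest", IRF), tuned by coarse-to-fine grid search under 10-fold
   cross-validation,
6. quantization of the predicted level to a control value in
   {0, 0.25, 0.5, 0.75, 1} driving three headless game controllers.

## Wavelet multiresolution analysis

### Why a discrete dyadic transform

The band layout this pipeline relies on — six subbands whose edges sit at
128/64/32/16/8/4 Hz — is exactly the dyadic partition produced by a
five-level Mallat cascade at fs = 256 Hz. A truly continuous wavelet
transform has no finite subband list and no detail/approximation
coefficient sets, so the package implements the discrete DWT/MRA: analysis
filters derived from the Daubechies scaling filter, downsampling by two per
level, and the exact inverse cascade. db4 (four vanishing moments, eight
taps) balances compact support — important when a 256-sample epoch is split
five times — against frequency selectivity.

The scaling filter is constructed at run time by spectral factorization of
the Daubechies polynomial (minimum-phase root selection), so db1–db10 are
available as an extensibility hook; db4 is the default and the only basis
the attention pipeline uses.

### Boundary handling and numerical guarantees

Two extension rules are implemented:

* `symmetric` (default): half-sample symmetric extension by one filter
  length per step, matching the convention of the major Python/Matlab
  wavelet toolboxes. Redundant (coefficient counts are ⌈(n+7)/2⌉ per step)
  but artifact-poor at epoch edges. Perfect reconstruction is exact to
  machine precision; the test suite enforces ≤ 1e-8 relative L2 error over
  lengths 64–4096.
* `periodic`: a circulant, exactly orthonormal transform (n/2 coefficients
  per step, length divisible by 2^L required). Energy conservation
  (Parseval) holds to machine precision and is tested at ≤ 1e-6 relative
  error. This mode exists because orthonormality is only exactly testable
  without boundary redundancy.

Signals shorter than 2^L + 1 samples are rejected with the required
minimum in the error message. The per-band reconstructions are linear, so
the sum of all six subband reconstructions reproduces the input; this is a
tested invariant.

### Denoising

The noise scale is estimated once per epoch channel as
σ = median(|D1|)/0.6745 — the MAD rule on the finest detail level, which is
dominated by broadband noise. Each detail level j is then soft-thresholded
at t_j·σ, where t_j minimizes Stein's unbiased risk estimate over the
candidate set {|c|/σ} (ties toward the smaller threshold, so an all-zero
level keeps threshold 0). Approximation coefficients are never touched.
When σ is numerically zero (noise-free or constant input) the
decomposition is returned unchanged rather than dividing by zero. The
suite checks the chosen threshold against a brute-force risk-curve oracle
and verifies SNR improvement on sinusoid-plus-noise inputs across 20 seeds
at 0–10 dB input SNR.

## Band-power features

The "PSD feature" of a band is the mean squared amplitude of its
band-limited reconstruction over the epoch — one number per channel and
band, with D1 (64–128 Hz) discarded as noise. This estimator was chosen
over Welch/multitaper spectra because it needs no windowing parameters and
inherits the denoising already applied to the coefficients.

Defaults and their rationale:

* `log_transform = TRUE`: features are log10(power + 1e-12). Band powers
  span orders of magnitude; the log stabilizes tree splits and any
  downstream linear baseline. The epsilon bounds the zero-power case
  (log10 → −12) without affecting realistic magnitudes.
* `relative = FALSE`: absolute power is the default; per-channel relative
  power (each channel's five bands summing to 1) is available behind the
  flag.
* Channel order is fixed to TP9, AF7, AF8, TP10 and features are
  channel-major, so feature index = 5·(channel−1) + band is deterministic
  and the CSV header (`TP9_delta`, …) is validated on read.

A caveat the tests make explicit: db4 subband reconstructions roll off
near the dyadic edges, so a band-center sinusoid keeps roughly 80–85% of
its energy in its own subband, and simultaneous tones leak a few percent
into neighbors. Band *dominance* (the right channel-band feature is the
maximum) is exact and tested against an FFT oracle; the analytic
amplitude²/2 identity is tested on the generator via the FFT measure, with
only an order-of-magnitude bracket through the wavelet path.

## The improved random forest

Trees are CART classifiers: at each node `max_features` candidate features
are drawn without replacement, all midpoints between sorted distinct values
are scanned, and the split minimizing the children's Gini impurity is
taken. Growth stops at purity or when `min_samples_leaf` forbids a split;
there is no pruning. Tie-breaking is fully deterministic: a split must
improve impurity strictly (tolerance 1e-12), candidates are scanned in
ascending feature index and threshold order, and leaf classes resolve ties
toward the lower ordinal level. The tree builder is compiled (Rcpp) but
draws its randomness from R's RNG, so `set.seed()` governs everything; the
R test suite contains an independent brute-force CART oracle that the
compiled trees must match exactly.

Each of the k trees trains on its own bootstrap sample (size n, with
replacement) with its own derived seed; prediction is simple majority
voting with ties toward the lower level (the conservative choice for an
attention monitor: ambiguity should not inflate the feedback signal).

### Grid search

The coarse phase scores every point of the coarse grid by mean S-fold CV
accuracy. Each refinement phase re-grids the incumbent's ± one-coarse-step
neighborhood at step 2 and scores all of its points; two phases are the
default, more are available. Two design details matter:

* Per-point seeds are derived from the hyperparameters themselves, not
  from evaluation order, so a point's score is reproducible in isolation —
  this is what lets the acceptance suite re-score every visited point
  independently and check the returned optimum exhaustively.
* Equal scores resolve to the smallest complexity key, ordered
  (n_estimators, max_features, min_samples_leaf). A penalty-style "smallest
  wins" rule needs a well-defined complexity ordering in a forest; tree
  count dominates cost, hence first.

The default coarse grid (n_estimators 50–300 by 50, max_features 2–20 by 2
capped at the feature count, min_samples_leaf {1, 3, 5, 9}) reflects common
forest practice; tests and examples pass smaller grids to stay fast. After
the search, the final model is refit on the full training set with the
winning hyperparameters (the CV models are discarded).

Cross-validation folds are a random partition into S disjoint,
near-equal-size folds (sizes differ by ≤ 1); disjointness and coverage are
property-tested across random (n, S).

## Neurofeedback control

The quantizer maps levels 0–4 to {0, 0.25, 0.5, 0.75, 1}; it is strictly
monotone by construction and tested as such. One tick = one classifier
prediction; the library has no real-time clock.

* **Sustained** (tug of war): advance iff control > threshold (strict —
  sitting exactly at the threshold is not enough), default threshold 0.5;
  the session is won when net advances reach the margin (default 10
  ticks). `win_time` is the winning tick count, `NA` if never reached.
* **Selective** (bird flight): control ≥ 0.75 → up (+1), 0.5 → level,
  ≤ 0.25 → down (−1). The obstacle course is a per-tick floor; the default
  is a ramp rising one unit every 8 ticks from −4, with no ceiling. The
  no-ceiling choice is deliberate: it makes "more attention is never
  worse" a theorem (higher control ⇒ pointwise higher altitude ⇒ no
  earlier collision), which the dominance tests rely on. `game_score` is
  ticks survived.
* **Focus** (skill release): the skill fires only at control value exactly
  1; `skill_times` records the 0-based release ticks.

The three-way selective mapping and the course/margin defaults are this
package's design choices — only the monotone coupling of direction to
attention is externally constrained. All controllers are pure functions of
(stream, config), so session logs are reproducible and the stochastic
dominance property (a pointwise-higher level stream never yields a worse
indicator in any game) is property-tested.

## Synthetic data: what it does and does not establish

`generate_epoch()` builds each channel as a sum of five band-center
sinusoids — 2, 6, 12, 24, 48 Hz, chosen inside the dyadic subbands to
minimize edge leakage — with independent random phases per channel, plus
white Gaussian noise. The default class profile (amplitudes in µV):

| class | delta | theta | alpha | beta | gamma |
|---|---|---|---|---|---|
| low | 20 | 18 | 10 | 4.0 | 2.0 |
| medium-low | 20 | 15 | 10 | 6.5 | 3.5 |
| medium | 20 | 12 | 10 | 9.0 | 5.0 |
| medium-high | 20 | 9 | 10 | 11.5 | 6.5 |
| high | 20 | 6 | 10 | 14.0 | 8.0 |

with noise sd 5 µV. Beta/gamma rise and theta falls with attention —
the direction follows the standard theta/beta-ratio convention; only the
existence of band–attention correlations is externally given, the sign
pattern and magnitudes are this package's modeling choice, fixed once
(amplitudes span a realistic 2–20 µV, adjacent classes differ by roughly
one noise-band standard deviation in log power). A `separation`
multiplier scales the class spread; `separation = 0` collapses all classes
(chance-level data for negative controls), and separability is monotone in
it, which drives the forest monotonicity test.

The generator emulates exactly the structure the pipeline assumes —
band-limited power that varies monotonically with class, plus broadband
noise — and nothing else: no 1/f background, no eye-blink or movement
artifacts, no inter-subject variability, no label noise. A green test
therefore establishes that the implementation is correct, not that the
method reaches any particular accuracy on recorded EEG. The acceptance
suite verifies ≥ 0.9 mean 10-fold CV accuracy on the default profile
(n = 250) and chance-level accuracy on the degenerate profile; those are
statements about this stated synthetic world.

## Numerical and degenerate-input policy

* Perfect reconstruction ≤ 1e-8 relative L2; energy conservation
  (periodic mode) ≤ 1e-6; feature-CSV round trip ≤ 1e-12 relative
  (values written with 17 significant digits).
* SURE ties → smaller threshold; split ties → lowest feature index, then
  smallest threshold; vote ties → lower attention level; grid ties →
  smallest complexity key.
* Empty coefficient sets, empty label vectors, all-zero confusion
  matrices, S > n fold plans, and dimension mismatches raise errors naming
  the offending quantity; a recording shorter than one epoch yields an
  empty epoch list with a warning (not an error) so batch jobs skip short
  files gracefully.
* A paired t-test with zero-variance nonzero differences reports the
  machine floor as its p value and is flagged `degenerate` instead of
  dividing by zero.
* All randomness flows from one master seed through named substreams
  (per tree, per fold, per grid point), all below 2^31.

## Known limitations

* The wavelet path's band powers are biased low by filter rolloff
  (~15–20% at band centers); classification is unaffected (the bias is
  class-independent), but the features should not be read as calibrated
  absolute band power.
* Baseline classifiers in `compare_classifiers()` are limited to k-NN,
  LDA, and a majority-class dummy — margin-based and boosting baselines
  would require packages outside this package's dependency footprint.
* The EDF reader covers continuous 16-bit EDF/EDF+ with one sampling rate
  across signals; discontinuous EDF+D files and annotation channels are
  out of scope.
* Epoch duration (1 s), overlap (0), and the per-epoch feature convention
  are defaults chosen for real-time feasibility, not externally fixed;
  they are configurable.
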