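---
title: "Motor-imagery EEG decoding with mibci: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery EEG decoding with mibci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibci)
```

## The decoding problem

Motor imagery (MI) — mentally rehearsing a limb movement without executing
it — attenuates the amplitude of the sensorimotor μ (8–13 Hz) and β
(13–30 Hz) rhythms over the contralateral motor cortex (event-related
desynchronization, ERD).  A two-class MI brain–computer interface must
therefore detect, trial by trial, on which side and in which band the
rhythm power dropped.  `mibci` implements that detection as a feature-based
pipeline: band-limited preprocessing, a hybrid time/time–frequency feature
description of each cue-locked epoch, optional hybrid feature selection,
and cross-validated classification.

This vignette documents the model choices, the tunable parameters and
their defaults, the numerical decisions, and what the synthetic test bed
does and does not establish.

## Preprocessing

The stage order is fixed: band-pass → normalize → notch → segment.

**Band-pass.** A 5th-order Butterworth IIR band-pass at 10–30 Hz, applied
forward–backward (`signal::filtfilt`) so the net filter has zero phase and
cue-locked timing is preserved.  A Butterworth design is the conventional
choice for extracting μ/β rhythms; the zero-phase application means the
effective magnitude response is the square of the single-pass response,
which is why the order parameter (`filter_order`, default 5) refers to the
underlying design, not the effective roll-off.  The 10 Hz lower edge
keeps the upper μ band and discards posterior α leakage and slow drifts;
30 Hz caps the β range and excludes most EMG.

**Normalization.** Each channel is z-scored over the full continuous
recording, using the population (divide-by-M) standard deviation.
Normalizing before segmentation matters: per-epoch normalization would
destroy the between-trial power differences that carry the class
information, while recording-level normalization only removes inter-channel
gain differences.  Population moments are used for consistency with the
sub-band statistics (all of which are population moments).  A constant
channel is a hard error naming the channel, never a silent NaN.

**Notch.** A second-order constrained biquad notch (quality factor 30,
i.e. a −3 dB width of 2 Hz at 60 Hz), also zero-phase.  It exists for
recordings contaminated by line interference; data that arrive pre-notched
are handled by `notch_hz = NULL`.  The `preprocess()` wrapper additionally
skips the notch when the configured frequency is at or above Nyquist
(e.g. a 60 Hz notch on a 100 Hz recording), since there is then no line
component to remove.

**Segmentation.** One trial per cue marker, using the half-open 0-based
sample window `[round((cue_s + start)·fs), round((cue_s + end)·fs))`.
Because cues land on integer samples, every trial has exactly
`round((end − start)·fs)` samples — 300 samples for the default
(0.5, 3.5) s window at 100 Hz, 500 for a (3, 8) s window.  Windows that
leave the recording raise an error listing the offending markers.

## Feature extraction

### Time-domain block (6 per channel)

Per trial and channel, computed on the full band-passed epoch: RMS,
quadratic Rényi entropy, Hjorth mobility and complexity, waveform length,
and mean absolute value.  Three decisions deserve notes:

* **Rényi entropy** is defined on a probability distribution, so the
  samples are first mapped to their normalized energy distribution
  `p_j = y_j² / Σ y²`; the entropy `log(Σ p^q)/(1 − q)` (natural log) then
  lies in `[0, log M]` and is amplitude-invariant.  Applying the power sum
  to raw signed samples would be ill-defined for non-integer orders.  The
  order `q` defaults to 2, the standard quadratic choice in EEG work, and
  is exposed as `renyi_q`.
* **Hjorth derivatives** are plain first differences, not scaled by `fs`.
  The scaling cancels exactly in complexity and multiplies mobility by a
  constant shared across all trials, so it cannot affect any classifier.
* **Hjorth activity** (the variance) is not part of the default layout —
  the default block is exactly six statistics — but is available via
  `include_activity = TRUE` and via the alternate wavelet layout below.

### Wavelet packet block (96 per channel)

Each epoch/channel is decomposed with a 4-level wavelet packet transform:
both the approximation and the detail branch are split at every level,
yielding `2^4 = 16` terminal sub-bands of equal nominal width (fs/32 Hz
each).  The transform is periodized and orthogonal: the analysis operator
is an orthogonal matrix, so coefficient energy equals signal energy and
the inverse transform is exact to round-off — both properties are asserted
in the tests rather than assumed.

* **Wavelet family**: Daubechies-4 (`db4`) by default, the standard family
  in EEG wavelet-packet work; `db1`, `db2` and `db8` ship as well
  (`wavelet_filter()`), all as hard-coded orthonormal filter banks.
* **Node ordering** is frequency-ascending.  Decimating a high-pass branch
  mirrors its spectrum, so the natural tree order interleaves frequencies;
  the binary-reflected Gray-code permutation restores physical order,
  which the adjacent-band ratio below presumes.  A probe tone at any node
  center lands in the right node (argmax over node energies) for all 16
  nodes; note, though, that finite filters leak part of a tone's energy
  into one aliasing-partner band, so the single-node energy share is
  ≥ 80% only away from the tree's interior (the top two nodes always hold
  ≥ 85%).
* **Odd node lengths.** Epoch lengths need not be divisible by `2^level`
  (300 is not).  An odd-length node is padded with a single zero before
  splitting; energy conservation and (truncated) perfect reconstruction
  remain exact, at the cost of a few extra coefficients.
* **Statistics per sub-band**: absolute mean μ, average power P_av,
  population SD σ, adjacent-band absolute-mean ratio γ, skewness and
  non-excess kurtosis (population standardized moments).  σ and the two
  higher-order moments are centered on the arithmetic mean.
* **The γ layout question.**  An adjacent-band ratio naturally yields
  `2^level − 1` values, one per interior adjacency — but that leaves one
  statistic short of six per node.  The default layout closes the ring
  cyclically (`γ_last = μ_last/μ_first`), giving exactly one γ per node,
  six statistics per sub-band, and the width law
  `columns = channels × (6 + 6·2^level)`: 1836 columns for 18 channels,
  1326 for 13.  The documented alternative
  (`wpd_layout = "adjacent-gamma-plus-activity"`) keeps the 15 interior
  ratios and adds the Hjorth activity time feature, which sums to the same
  102 per channel.

### Fusion

`fuse_features()` concatenates time block first, then the wavelet block,
checks trial-count alignment and name uniqueness, and attaches the labels.
Feature names are canonical and parseable:
`CH:<label>|<domain>|<subband-or-NA>|<stat>`, e.g. `CH:C3|wpd|b07|sigma`.

## Hybrid feature selection

A 1836-column matrix estimated from a few hundred trials is heavily
overparameterized; selection serves both accuracy and run-time (a handful
of features classify faster than two thousand).

**Filter stage (CFS).**  Subset merit
`k·r̄_cf / √(k + k(k−1)·r̄_ff)` rewards features correlated with the class
(point-biserial, since the label is binary) and penalizes features
correlated with each other (Pearson, absolute values).  The search is
best-first from the empty set with single-feature expansions, stopping
after 5 consecutive expansions that fail to improve the best merit — the
canonical stopping rule for this filter.  Ties break toward the lower
column index, so the search is deterministic.  Feature–feature correlation
columns are cached lazily, which keeps the filter fast on wide matrices.

**Wrapper stage.**  Forward stepwise search over the filter survivors,
scored by stratified inner-CV accuracy of the configured classifier
(default: 10 folds, linear SVM).  Each round accepts the best
strictly-improving addition and stops at the first round with no strict
improvement, so the accuracy trace is strictly increasing and termination
is guaranteed.  The empty-model baseline is the majority-class rate.

**Nesting.**  Inside `crossvalidate()` and `run_experiment()` the whole
hybrid selection is refit on each outer training fold; the outer test fold
never influences which features are kept.  This costs a factor of
`folds` in run time but removes selection bias from the reported accuracy —
on a null-effect dataset the nested pipeline scores at chance, which is
asserted in the acceptance tests.  The unnested protocol (select once on
all trials, then cross-validate) is available as `nested_fs = FALSE` (CLI
`--leaky-fs`) for comparison with selection-then-validate studies; its
accuracy estimates are optimistically biased and it should not be used for
reporting.

## Classification and evaluation

Three backends, all on features standardized by training-fold statistics:

* **linear SVM** (`e1071::svm`, cost `C = 1`), score = signed margin;
* **LDA** (`MASS::lda`), score = posterior difference; when the pooled
  covariance is singular (e.g. duplicated columns) a ridge-regularized
  pooled-covariance LDA (`λ = 10⁻³·mean(diag Σ)`) takes over, with a
  message;
* **k-NN** (`class::knn`, Euclidean), `k = 5` — odd by construction so
  two-class votes cannot tie; score = positive-vote fraction.

`C`, `k` and the LDA fallback are conventional defaults, exposed in
`pipeline_config()`; on the synthetic fixtures results are insensitive to
them.  The positive class is the lexicographically larger label unless
overridden, which fixes the orientation of sensitivity/specificity and of
all scores.

Folds are stratified within class from a seeded shuffle.  Plain random
splitting risks single-class folds at small n; stratification is the one
deliberate divergence from a purely random split and is noted here for
that reason.  Metrics follow the standard confusion-matrix definitions,
with zero-denominator cases reported as `NA` rather than 0.  AUC is the
normalized Mann–Whitney statistic on the continuous scores (ties count a
half), which equals the trapezoidal area under the ROC curve; hard labels
are never used for AUC.

## The synthetic test bed

`generate_recording()` emulates the physics the classifier exploits and
nothing more: per channel, 1/f background noise (FFT-shaped, exponent 1,
RMS 0.5) runs continuously; within each 4 s trial, band-passed white noise
in 8–13 Hz and 13–30 Hz (RMS 1 each) is added, and on the informative
channels its amplitude is scaled by `1 ± effect/2` with the sign depending
on the class, lateralized over the two halves of the informative-channel
set.  Trials alternate with 1 s gaps; markers sit at trial onsets;
everything derives from one seed.  At `effect = 1` the class-wise band
power ratio on an informative channel is `(1.5/0.5)² = 9`, and with the
background amplitude at half the oscillation amplitude that ratio is
observable in a periodogram to within 20%, which the generator tests
assert.  Optional 60 Hz line interference is available when `fs` exceeds
120 Hz (the notch fixture uses 250 Hz).

Defaults (100 Hz, 4 s trials, (0.5, 3.5) s epochs → 300-sample trials,
oscillation-to-background amplitude ratio 2) were chosen once as a
strong-ERD regime and are not tuned per test.

**What passing tests show — and don't.**  The generator produces
stationary, Gaussian, spatially independent channels with a literal
amplitude contrast.  Real MI-EEG adds volume conduction (correlated
channels), non-stationarity, eye/muscle artifacts, and subject-specific
band edges; none of these are modeled, so the near-perfect accuracies on
the strong-effect fixture say the pipeline is *correct*, not that any
particular accuracy will transfer to recorded data.  The null-effect
fixture is the converse control: the full nested pipeline must score
within the binomial 95% interval of 0.5, which would fail under feature
or selection leakage.

## Problem sizes used by the shipped checks

The acceptance tests and `scripts/acceptance.R` use 200-trial fixtures
(100 per class, 18 channels) for the strong- and null-effect end-to-end
runs, 100-trial recordings for the effect-size sweep
(`effect ∈ {0, 0.25, 0.5, 1}`), and ten 100-trial seeds for the
informative-channel recovery check (2 informative channels of 18,
asserting that ≥ 60% of selected features come from them).  These sizes
give binomial confidence intervals tight enough for the stated bounds
while keeping a full run in the tens of seconds on one core.

## Known limitations

* Binary tasks only; multiclass MI would need one-vs-rest wrappers around
  `train_predict()`.
* No artifact rejection beyond filtering (no EOG/EMG regression, no ICA).
* The EDF reader covers the 16-bit EDF/EDF+ subset the pipeline needs
  (uniform sampling rate across data signals, annotation-based markers);
  it is not a general EDF implementation.
* Wavelet sub-band edges are nominal: finite Daubechies filters overlap,
  so adjacent sub-band statistics are correlated — one reason the CFS
  redundancy term earns its keep.
* Feature selection is per run; no cross-subject transfer or per-subject
  calibration logic is included.
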