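---
title: "Critical spectral verge features for pre-ictal EEG classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical spectral verge features for pre-ictal EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spectralverge)
```

## The problem

Epileptic seizures are preceded, in many patients, by minutes of altered
cortical dynamics — the *pre-ictal* (PIL) state — that are visible in scalp
EEG, particularly as shifts of power toward high-frequency (gamma) activity
and high-frequency oscillations (HFOs). A seizure *prediction* system
watches a multichannel EEG stream and classifies short windows as pre-ictal
or inter-ictal (IIL); a run of pre-ictal decisions raises an alarm some
minutes ahead of the onset. This package implements such a pipeline
end-to-end: signal cleaning, a compact frequency-domain feature, a small
convolutional classifier, and alarm-level evaluation, together with a
synthetic EEG generator that plants the statistical structure the method is
designed to detect.

## Multiresolution adaptive filtering (MRAF)

Each channel is cut into non-overlapping 4-s segments (`segment_eeg()`;
`window_samples = round(4 * fs)`, trailing partial segments discarded).
Each segment is denoised by a discrete wavelet transform (db4 by default,
symmetric boundary extension, `floor(log2(n)) - 2` levels) with soft
thresholding of every detail level at the universal threshold

\[ Z_l = \sigma \sqrt{2 \ln P}, \]

where \(P\) is the segment sample count. The noise scale \(\sigma\) is
estimated robustly as `mad(finest detail level) / 0.6745`. Taking each
level's own coefficient standard deviation as \(\sigma_l\) instead would
shrink signal-bearing levels in proportion to their own energy and destroy
clean oscillations entirely (a pure sinusoid has no coefficient above
\(1.5\sigma\) of its own level, let alone \(3.7\sigma\)); the finest level
is noise-dominated in EEG sampled at 200 Hz and above, which makes it the
standard estimator for this threshold. `universal_threshold()` exposes the
bare formula for testing and accepts an explicit `sigma`.

The denoised segment is then split into the clinical bands — alpha 8–13,
beta 13–30, gamma 30–100 (capped at Nyquist), theta 4–8, delta 0.5–4 Hz and
the full band — one filtered signal per band. The band stage is an
8-tap normalized-LMS adaptive FIR filter (step size \(\mu = 0.01\),
zero-initialized weights) whose *input* is the exact FFT band-limitation of
the denoised segment and whose *reference* is the denoised segment itself:
the filter output \(D_o(u) = \sum_{i=0}^{s-1} w_i(u)\, x(u-i)\) is causal
in its input, adapts its gain to the segment, and — because an FIR filter
cannot create frequencies its input lacks — stays inside the band. We
considered selecting whole DWT scales as the band reference instead, but
octave scale edges (…, 7.8, 15.6, 31.2 Hz …) misalign with every clinical
band boundary (beta 13–30 Hz spans parts of two octaves and would drag
along alpha content), which breaks the requirement that at least 90 % of a
band output's power lie inside the band. The spectral band-limitation is
therefore the documented reference-signal choice. The full band (`fb`) is
the pass-through of the denoised signal.

Tunable parameters (YAML keys of the `features` block): `window_s` (4 s),
`wavelet` (db4), `levels`, `taps` (8), `mu` (0.01), and the band list.
A 1040-sample window equals 4 s exactly at 260 Hz; at other rates the 4-s
duration is honored.

## The critical spectral verge (CSV)

For every band, segment and channel a one-sided periodogram is computed
with zero-padding to a bin spacing of at most 0.1 Hz, scaled so that
summing `power * df` over the frequency axis returns the segment variance.
The *spectral verge* (SV) is the highest frequency whose power strictly
exceeds the band's mean power — a one-number summary of how far toward the
band's upper edge above-average activity reaches. Ties at exactly the mean
are excluded; a degenerate flat spectrum falls back to the arg-max bin.

The SV is refined into the *critical* spectral verge by maximizing the
objective

\[ f(m) = \begin{cases} m & \text{if } YS(\mathrm{bin}(m)) > \overline{YS} \\ -10^6 & \text{otherwise} \end{cases} \]

over the band's own frequency range with a flower-pollination optimizer
(population 20, switch probability 0.8, Mantegna Lévy flights with
exponent 1.5, 100 iterations — the canonical hyperparameters of that
algorithm). The penalty constant rather than bin removal keeps the search
space continuous. The SV enters the initial population verbatim and
best-ever bookkeeping is used, so the returned fitness can never fall
below the seed's; on a piecewise-constant-per-bin objective the optimizer
provably agrees with exhaustive grid search to within one bin, which the
test suite checks on random spectra. Search bounds are each band's own
`[f_lo, f_hi]` — a verge outside its band would be meaningless in the
feature map — and the full band searches up to Nyquist. Maps are computed
per channel; per-channel rows are stacked (not averaged) into the
classifier input, preserving spatial information.

The feature map for one record is the `bands x segments` matrix of CSV
frequencies per channel, in the row order alpha, beta, gamma, theta,
delta, full band.

## The classifier

Classification windows cover `width` consecutive segments (stride
`stride`); their feature-map slices are stacked into a
`channels x bands` tall input plane, standardized per feature row with
statistics fitted on training windows only. The network is deliberately
small: conv 3x3/8 (stride 1x1) → maxpool 2x2 → conv 5x5/16 (stride 1x3)
→ maxpool 2x2 → conv 3x3/32 (stride 1x3) → dense 256 → dense 128 → dense
2, ReLU throughout, dropout 0.5 after the first two dense layers, softmax
output. Convolutions use 'same' padding so the input height survives the
stride chain; pooling floors odd dimensions. Training uses Adam
(learning rate 0.001, default moment constants), categorical
cross-entropy, mini-batches of 100, at most 150 epochs, and early
stopping once the validation error rate has risen for 10 consecutive
epochs, restoring the best-validation weights. The validation "error
rate" is 1 − accuracy on the held-aside split. All of forward/backward is
implemented with im2col sparse-gather matrix products; gradients are
verified against finite differences in the test suite.

A parallel *sub-band voting* path trains one such network per band (input
height = channels) and fuses hard labels by majority vote, ties resolved
toward inter-ictal so that ambiguity never raises an alarm. The ablation
switches are: `no_multiresolution` (raw-segment full-band periodogram
features, single band row, no filtering), `no_subband_voting` (average the
stream probabilities instead of voting), and `shallow` (drop the third
conv layer).

## Class imbalance

Pre-ictal minutes are rare — about 15 inter-ictal minutes per pre-ictal
minute in long recordings — so training folds are rebalanced by random
oversampling (default), random undersampling, or borderline-SMOTE
(variant 1: synthetic points interpolate "danger" minority points, whose
neighborhood is majority-dominated but not engulfed, toward minority
neighbors). Resampling touches training folds only; synthetic rows are
clipped to the per-feature band ranges when those are attached. With no
danger points, interior minority points are interpolated; with a minority
smaller than the neighborhood the method falls back to oversampling with
a warning.

## Alarm evaluation

A window is labeled pre-ictal when its span intersects
`[onset - 5 min, onset)` (clipped at the record start); windows touching
ictal time are excluded from training and testing, since the task is
PIL-vs-IIL. An alarm fires at the end of the `persistence`-th consecutive
window whose PIL probability exceeds the threshold, and is followed by a
refractory period (default: one SOP) suppressing duplicates. Under
SPH/SOP semantics an alarm at time \(t\) is a true positive when some
onset lies in \([t + \mathrm{SPH},\, t + \mathrm{SPH} + \mathrm{SOP}]\);
onsets are credited greedily in time order, at most once. An alarm whose
seizure begins inside the SPH is a false positive *and* that seizure, if
never properly predicted, a false negative — so TP + FN always equals the
seizure count. Sensitivity and FPR/h are event-level; the accuracy of
Eq.-style window counting is reported separately at window level, since
the two granularities must not be mixed silently. Inter-ictal hours for
the FPR denominator are total record time minus pre-ictal, ictal, and
post-alarm (SPH+SOP) spans, overlaps merged. AUC is the rank
(Mann–Whitney) statistic of the PIL probability. Protocols: stratified
80/20 holdout with repeated seeds, leave-one-seizure-out, and
leave-one-patient-out folds, with leakage assertions in the tests.

## The synthetic generator

`simulate_record()` emulates what the method assumes about clinical data:
21 channels (10–20 montage names) at 250 Hz and 16-bit quantization by
default; per-channel 1/f-colored background noise (steeper roll-off above
25 Hz) plus five band-limited noise components with a shared sinusoid per
band at a random per-channel phase (delta 2, theta 6, alpha 10, beta 20,
gamma 40 Hz; relative powers 1 / 0.6 / 0.8 / 0.4 / 0.3). Inside each
pre-ictal span the gamma component's power is multiplied by
`preictal_gamma_gain` (default 4) and HFO-like tone bursts (78–92 Hz,
~0.4 s, ~1.2 per second) are added, so pre-ictal segments carry both a
gamma power elevation and a raised gamma-band spectral verge. Ictal time
is a large 3.5-Hz spike-wave discharge, generated for realism but always
excluded from classified windows. Optional artifacts are blink-like
biphasic transients (< 2 Hz, high amplitude) and broadband muscle bursts
at Poisson times. Everything is reproducible from one integer seed.

What the generator does *not* model: volume conduction and inter-channel
correlation structure, patient-specific seizure morphology,
non-stationary drift, electrode pops, mains interference. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers a
planted, physiologically-motivated effect under realistic noise and
imbalance — not clinical-grade performance on real EEG.

## The scaled-down end-to-end experiment

`run_synthetic_experiment()` evaluates the whole chain under
leave-one-seizure-out cross-validation on a cohort of 6 synthetic
single-seizure patients, 20 minutes and 3 channels each, gamma gain 4,
and an exact 15:1 inter-ictal : pre-ictal ratio. Twenty-minute records
and a 15:1 ratio jointly force a 1.25-minute pre-ictal period (75 s =
20 min / 16); the alarm clock is scaled alongside — SPH 15 s, SOP 2.5
min, persistence 2 — because an alarm raised from a 75-s pre-ictal lead
cannot honor a 5-minute horizon. The 5-minute PIL / 5-minute SPH /
10-minute SOP defaults remain the package defaults for full-length data.
Per fold, scaling, resampling (ROS) and threshold tuning (Youden's J on
training windows, ties toward the higher threshold) see training folds
only; the classifier trains for at most 40 epochs here, which is several
times past convergence on this task. Three channels are used because the
generator's channels are statistically exchangeable — more channels add
computation, not information, to a property-style check.

## Numerical choices and degenerate inputs

* DWT: symmetric extension with redundant boundary coefficients, hence
  exact reconstruction (verified to 1e-8 in tests); "log" in the
  threshold is the natural logarithm (the base-10 reading would shrink
  thresholds ~2.3-fold).
* Segment count is `floor(samples / window_samples)`; the alternative
  reading "samples / fs" does not yield a segment count for any window
  other than 1 s and is not used.
* Periodogram: zero-padding to the next power of two above
  `fs / 0.1 Hz`; demeaned segments; one-sided scaling checked by
  Parseval within 5 %.
* Flat spectra: the spectral verge falls back to the arg-max bin; the
  objective's nearest-bin lookup clamps at the band edges.
* EDF: symmetric digital range ±32767 so that zero is representable
  exactly and round trips are within one quantization step; physical
  ranges are whole microvolt bounds so the 8-character header fields are
  exact.
* Ties: majority vote → inter-ictal; threshold tuning → higher
  threshold; pooling argmax → first element.
* Quantization uses each channel's own range, like per-channel gain in
  acquisition hardware.

## Known limitations

The CNN is CPU-only and sized for feature maps, not raw EEG. The EDF
writer emits EDF+C with one annotation stream; channel-specific
annotation detail travels in the TUH-style sidecar CSV. The generator's
pre-ictal signature is a stand-in — real pre-ictal EEG is not
characterized by any single quantitative signature — so clinical claims
require clinical data. Cross-patient generalization is supported as a
protocol (`cross_subject_folds()`) but synthetic patients are exchangeable,
which makes that protocol easy here and hard in reality.
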