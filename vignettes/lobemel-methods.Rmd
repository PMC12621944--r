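---
title: "Lobe-resolved EEG classification: models, parameters and design choices"
author: "lobemel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lobe-resolved EEG classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lobemel)
```

This vignette is the package's own account of what it computes and why
the defaults are what they are. It covers the generative model behind the
synthetic cohorts, every pipeline stage with its tunable parameters, the
numerical corner cases, and what the passing test suite does — and does
not — establish about real EEG.

## 1. The question the pipeline answers

EEG electrodes are grouped by scalp region under the 10–20 system:
frontal (Fp1, Fp2, F3, F4, F7, F8, Fz), central (C3, C4, Cz), temporal
(T3, T4, T5, T6 on the classic 19-channel montage; T7, T8, TP7, TP8 on
the modern labels of the built-in dense-montage table), parietal (P3,
P4, Pz) and occipital (O1, O2). A *lobe-ablation* experiment runs the
identical classification protocol on each group and on the full montage;
if one region's channels support markedly higher accuracy, that region
carries the class-discriminative signal. `lobemel` packages this design
end to end, together with a synthetic-cohort generator whose planted
effect makes the correct answer known in advance.

## 2. The synthetic cohort model

`generateCohort()` draws, per subject and channel, an independent
1/f^α background ("pink" noise, α = 1 by default — the canonical
broadband EEG spectrum shape) at unit RMS, scaled to a nominal 10 µV.
ScZ subjects additionally receive one shared band-limited stochastic
oscillation — brick-wall-filtered Gaussian noise — summed into exactly
the channels of the configured effect lobes. Its sample RMS is
`effectSnr` × background RMS.

Defaults encode the emulated study conditions: 14 subjects per class
(a balanced 28-subject cohort), 15-minute recordings at 250 Hz on the
19-channel montage, an alpha-band (8–12.5 Hz) effect in the frontal
lobe. Band-power increases confined to a lobe and a physiological band
are the simplest generative account consistent with the lobe-ablation
premise; the frontal placement mirrors the region reported most
informative for this disorder, and alpha is a conventional choice of
carrier band. The effect amplitude has no empirical estimate to copy —
it is a free parameter. We fixed `effectSnr = 0.8` once: at 0.8 × the
background RMS the planted oscillation raises in-band channel power by
roughly 60 %, large enough that a correctly wired pipeline should
separate the classes from single 3-s segments yet far from a
deterministic, single-pixel giveaway.

Design choices worth knowing:

* **Stochastic, not sinusoidal, effect.** A fixed sinusoid would render
  as an identical spectrogram ridge in every segment; band-filtered
  noise varies in amplitude and phase across segments, so the classifier
  must learn a band/region pattern rather than one pixel.
* **Shared effect waveform across channels.** The only inter-channel
  covariance is the effect itself; background channels are independent.
  Volume-conduction-style mixing of the background is deliberately out
  of the model.
* **Determinism.** Per-subject sub-seeds are a fixed linear congruential
  mix of the master seed and the subject index, so `(spec, seed)`
  reproduces every sample bit for bit on any platform.

What the generator does **not** emulate: eye blinks and muscle/line
artifacts, event-related structure, inter-subject variability in
background slope or amplitude, and realistic channel covariance. Tests
that pass on these cohorts therefore certify the *pipeline's wiring*
(spatial selectivity, spectral rendering, fold hygiene), not clinical
performance on real recordings.

## 3. Preprocessing

`bandpassFilter()` applies a zero-phase (forward–backward) Butterworth
band-pass, default 0.5–45 Hz at order 2, independently per channel.
Zero-phase filtering leaves spectrogram timing undistorted; the
forward–backward pass squares the magnitude response, which is why the
60 Hz stopband test sees a gain far below the single-pass value. The
order-2 default matches the design used for the per-band decomposition;
the broadband filter adopts the same order for consistency. The filter
refuses signals shorter than three settling lengths of the 0.5 Hz
corner (~6 s at 256 Hz) rather than returning edge-dominated output.
At order 2 the transfer-function (b, a) form is numerically safe even
with the corner at 0.5/128 of Nyquist; higher orders would warrant a
second-order-section implementation.

`resampleRecording()` performs rational polyphase resampling
(anti-aliased FIR, via the `signal` package) and guarantees the length
contract `round(n · target/source)` exactly — 225 000 samples at 250 Hz
become 230 400 at 256 Hz. `segmentRecording()` cuts non-overlapping
3-s windows (768 samples at 256 Hz), drops the trailing remainder, and
propagates the recording's label to every segment — the standard
segment-inherits-label convention.

Pipeline order is filter → resample → segment: filtering at the source
rate keeps the anti-aliasing and band edges independent, and
segmentation last means segment boundaries never see filter edges.
Optional per-band filtering (delta 2–4, theta 4.5–7.5, alpha 8–12.5,
beta 13–30, gamma 30–45 Hz) is exposed via `preprocessRecording(band=)`
but is not part of the default path, which uses the broadband signal.

## 4. From segment to image

Each multichannel segment becomes one fixed-size image:

1. Per channel: one-sided STFT with a Hamming taper, `nFft = 256`
   (1 s at 256 Hz), `hop = 32`; squared magnitude.
2. Mel filter bank: 64 triangular filters whose centres are equally
   spaced on the mel axis `mel(f) = 2595·log10(1 + f/700)` between 0.5
   and 45 Hz (the filtered band). Adjacent triangles overlap by
   construction; a bank whose triangles are too narrow for the FFT
   resolution (an empty row) is refused with an explicit error.
3. Channel aggregation: the per-channel mel *power* spectrograms are
   averaged. Averaging happens in a canonical (sorted channel name)
   order so the image is bit-identical under any input channel
   permutation. How several channels should become one image is a
   genuinely open design point; power averaging keeps one
   time×frequency plane regardless of channel count (2 for occipital,
   19 for full), keeps images comparable across lobes, and preserves
   the planted band's relative elevation.
4. `log(power + 1e-10)` compression, per-image min–max scaling to
   0–255, bilinear resize to 224×224 (`EBImage`), and a fixed
   perceptually-uniform colormap (viridis; `"gray"` available) to RGB.
   Low frequencies sit at the bottom of the image, time runs left to
   right, and no axes or decorations are rendered — the classifier sees
   data only.

STFT/mel defaults are chosen so a 768-sample segment yields 17 frames
(time resolution ~0.125 s) and the 0.5–45 Hz range is resolved into 64
mel bands — enough that few-Hz-wide band effects span several image
rows. Two degenerate cases are pinned down: an all-zero (or constant)
spectrogram maps to mid-gray 128 rather than dividing by a zero range,
and scaling a segment by any positive constant leaves the image
unchanged (the log turns gain into an offset that min–max removes).

## 5. The classifier

`cnnConfig()` describes the fixed stack: four blocks of
(Conv2D 32 filters 3×3, stride 1, 'same' padding, ReLU → MaxPool 2×2
stride 2), dropout 0.25 after blocks 2 and 4, flatten, dense 256 ReLU,
dropout 0.5, dense 2 softmax. At 224×224×3 the feature maps shrink
224 → 112 → 56 → 28 → 14 and the parameter count is exactly 1,635,042
(896 + 3×9248 + 1,605,888 + 514); both numbers are locked by tests.
Input sides must be divisible by 16 so every pooling halves an even
size; at other sizes the dense layer's input derives from the resulting
flatten length (the `deskConfig()` 64×64 profile gives 4×4×32 = 512).

Training uses Adam (lr 0.001, β₁ 0.9, β₂ 0.999 — library-default
hyperparameters, recorded in `trainModel()`'s signature), categorical
cross-entropy on one-hot targets ordered (HC, ScZ), batch size 32,
100 epochs by default, and 1/255 pixel scaling. There is no early
stopping, augmentation or checkpointing. The implementation is the
package's own RcppArmadillo code — im2col plus BLAS sgemm in single
precision, Glorot-uniform initialisation, inverted dropout — with one
`mt19937` stream driving initialisation, shuffling and dropout, so a
fixed seed reproduces training exactly on a single thread. A probability
tie at exactly 0.5/0.5 resolves to ScZ, the positive class.

The reduced "desk" profile (64×64 inputs, 10 epochs, 5 folds) is the
package's standard experimental size for the synthetic studies: on the
planted-effect cohorts the class signal is strong enough that longer
training adds nothing, and the full 224×224/100-epoch/10-fold profile
remains available through the same configuration objects.

## 6. Evaluation

`makeFolds()` assigns stratified folds (class ratio within ±1 item per
fold) at either the segment or the subject level; subject-level folds
keep all of a subject's segments on one side of every split.
Segment-level splitting is the default because it mirrors the protocol
being studied — near-ceiling accuracies in this family of pipelines are
obtained with segment-level cross-validation — but subject-level folds
are the honest-generalisation setting and are recommended whenever a
claim about new subjects is intended; the two are one argument apart.

`confusionMetrics()` reports sensitivity, specificity, precision,
accuracy, F1 and FPR in percent with ScZ positive; zero-denominator
ratios surface as `NaN` with a warning, never as a silent 0. Fold
summaries are mean ± sample standard deviation (ddof = 1, the k-fold
convention). ROC curves sweep thresholds over the unique scores; the
region-level curve pools concatenated out-of-fold scores — a single
curve per region rather than a per-fold average. Fold seeds derive from
the master seed, so a whole `runLobeExperiment()` is reproducible.

## 7. Attribution

`gradCAM()` implements gradient-weighted class activation mapping over
the last convolutional layer: spatially averaged gradients of the
target-class score form channel weights, the weighted activation sum is
rectified, bilinearly upsampled and min–max normalised; an everywhere-
zero gradient yields an all-zero map with a warning rather than a
spurious normalisation. Channel-weighted maps assume the class evidence
is *channel-coded*; on tiny two-class networks a class can instead be
encoded by suppression of the other class's features or by
spatially-signed dense read-out, in which case that class's map is
uninformative — a known limitation of the method, not of the
implementation, and the reason the localization tests use a fixture
whose class evidence is carried by colour (channel) at a fixed location.

`limeExplain()` fits a ridge regression (penalty 0.01) to the model's
probabilities under random superpixel on/off masks, weighted by an
exponential kernel (width 0.25) on cosine distance from the unperturbed
mask. Superpixels are a fixed 8×8 grid by default — deterministic and
aligned with the mel axis — and masked regions are filled with the
per-channel image mean rather than black, which would be far outside
the distribution of log-power pixels. Positive-weight superpixels (P1,
P2, …) push towards the target class, negative ones (N1, N2, …) away;
both lists are ranked by |weight|. Both explainers are pure observers:
model weights and predictions are bit-identical before and after.

## 8. Problem sizes used by the tests and acceptance script

The synthetic structure-recovery study runs 8 subjects per class × 60 s
at 250 Hz (20 segments each, 320 images per region) with the desk
profile and 5 folds on the frontal, occipital and full montages; the
test suite repeats it over five run seeds and requires the ranking
conditions (frontal ≥ occipital + 15 points; occipital within 40–70 %;
full ≥ frontal − 5 points) in at least four. These sizes were chosen as
the smallest cohort at which chance-level occipital accuracy is
estimated with useful precision from 64 test segments per fold. Unit
tests use 16–32×32-pixel toys and short signals throughout.

## 9. Known limitations

* The background model is per-channel i.i.d. 1/f noise; correlated
  backgrounds (volume conduction, reference effects) would make the
  lobe ablation harder than our cohorts suggest.
* Segment-level cross-validation, the default here as in the protocol
  it mirrors, leaks subject identity across folds; use
  `unit = "subject"` for generalisation claims.
* The EDF writer quantises to 16 bits over a symmetric per-channel
  range (relative error ≤ ~3×10⁻⁵ of full scale).
* Grad-CAM maps for a class encoded purely by absence of the other
  class's features are legitimately blank-ish (see §7).
* The CNN runs on CPU in single precision; bit-exact reproducibility is
  guaranteed for a fixed seed on one thread, not across BLAS builds.
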