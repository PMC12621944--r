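# lobemel

Brain-lobe-resolved EEG classification with mel-spectrogram images and a
compact convolutional network.

## The problem

Resting-state and task EEG of schizophrenia (ScZ) patients differs from
healthy controls (HC) in band-limited power, but different scalp regions
carry very different amounts of that information. `lobemel` implements a
lobe-ablation pipeline for quantifying this: the channels of a 10–20
montage are grouped into frontal, central, temporal, parietal and
occipital lobes, the *same* classification protocol is run on each group
(and on the full montage), and the resulting accuracy ranking says which
lobe is informative. Attribution maps (Grad-CAM, LIME-style superpixel
explanations) then show *where* in the time–frequency plane the
classifier looks.

The pipeline is aimed at methodologists who want to study this design
under controlled conditions: a seeded synthetic-cohort generator plants a
band-limited class effect into chosen lobes on top of 1/f background
activity, so the spatial "ground truth" of the class difference is known
and the pipeline's ability to recover it can be measured.

## The method

1. **Preprocess** — zero-phase Butterworth band-pass 0.5–45 Hz (order 2),
   resample to 256 Hz, cut into non-overlapping 3-s segments (768
   samples).
2. **Montage** — select the channels of one lobe, or all 19 channels
   (`"full"`); a built-in table also realises a 19-of-64 channel
   selection for dense montages.
3. **Image** — per channel, a short-time Fourier transform (Hamming
   window, `nFft = 256`, `hop = 32`),
   `mel(f) = 2595 · log10(1 + f/700)`-spaced triangular filters
   (64 bands over 0.5–45 Hz), power averaged across channels,
   log-compressed, min–max scaled and rendered as a 224×224 RGB image
   (low frequencies at the bottom).
4. **Classify** — a four-block CNN (32 3×3 filters per block, 2×2 max
   pooling, dropout 0.25 after blocks 2 and 4, dense 256 with dropout
   0.5, softmax over HC/ScZ; 1,635,042 trainable parameters at 224×224),
   trained with Adam on categorical cross-entropy, pixels scaled by
   1/255.
5. **Evaluate** — stratified k-fold cross-validation (segment- or
   subject-level), six metrics in percent (sensitivity, specificity,
   precision, accuracy, F1, FPR) as mean ± sd over folds, pooled
   out-of-fold ROC/AUC, and a per-region accuracy ranking.
6. **Explain** — Grad-CAM over the last convolutional layer and a
   LIME-style ridge surrogate over grid superpixels.

## Worked example

```r
library(lobemel)

# a small cohort: 4 subjects/class, 60 s each, alpha-band (8-12.5 Hz)
# effect planted into the frontal lobe at 0.8 x background RMS
spec <- cohortSpec(nSubjectsPerClass = 4, durationS = 60,
                   effectLobes = "frontal", effectBandHz = c(8, 12.5),
                   effectSnr = 0.8, seed = 101)
cohort <- generateCohort(spec)

ex <- runLobeExperiment(cohort,
                        regions = c("full", "frontal", "occipital"),
                        config = deskConfig(),   # 64x64 images
                        k = 5, epochs = 10, seed = 1, verbose = TRUE)
ex$ranking
```

Output from this exact run:

```
region full     : accuracy 100.00%
region frontal  : accuracy 100.00%
region occipital: accuracy 50.00%
     region meanAccuracy
1      full          100
2   frontal          100
3 occipital           50
```

The frontal montage (where the effect was planted) and the full montage
classify almost perfectly, while the occipital channels — which carry no
class signal — sit at chance. That is the lobe-ablation logic in
miniature: the accuracy ranking recovers the spatial origin of the class
difference.

Individual stages are exported too:

```r
segs <- preprocessRecording(cohort[[5]])          # filter, resample, segment
img  <- segmentToImage(segs[[1]])                 # 224 x 224 x 3 MelImage
cam  <- gradCAM(model, img)                       # after trainModel(...)
lime <- limeExplain(model, img, seed = 1)
```

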