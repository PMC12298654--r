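# withdrawr

Automated, objective phenotyping of spontaneous opioid-withdrawal behavior
in rats from multi-view cage video and audio.

Preclinical withdrawal studies still score behaviors — wet-dog shakes,
scratching, rearing, grooming and other stereotypies, teeth chattering — by
eye, which is slow and poorly reproducible. `withdrawr` implements the full
automated chain for a five-camera (one top + four side) recording cage with
cage microphones:

1. **Motion filtering.** The top view collapses to a 1-D moving-pixel count
   signal \(c_t = \#\{p : |I_{t+1}(p) - I_t(p)| > \tau\}\) (default
   \(\tau = 25\)); envelope/baseline segmentation
   (\(\mathrm{env} - \mathrm{base} > k\,\hat\sigma\), morphological closing,
   merging, padding) keeps only motion segments and discards >80% of frames.
2. **Pose and camera selection.** The first frame of each segment is
   cleaned by erosion/dilation (removing the tail), an ellipse is fitted
   from second-order image moments, and the side camera most perpendicular
   to the body axis (nearest wall, then lowest id, as tie-breaks) is
   selected — 25% of the side-stream data, ~5% of frames overall reaching
   recognition.
3. **Rhythmic detection.** Wet-dog shakes and scratching are peak trains in
   \(c_t\): permissive prominence-based screening, then strict tests on peak
   count, duration, inter-peak interval (6–16 Hz band for shakes), height
   and interval regularity, dominant frequency and spectral concentration
   for scratch trains.
4. **Clip classification.** Side-view key frames (the *k* = 9
   highest-motion frames of a segment) are classified by an
   attention-augmented convolutional feature extractor — sequential CBAM or
   the parallel-fusion CSPM block (spatial kernel 3 or 7) — with a trained
   multinomial readout and per-clip majority vote; Grad-CAM heatmaps expose
   what the classifier used.
5. **Audio.** Recordings are cut into 5 s clips; median + bandpass
   filtering, Hilbert-envelope gating, decimation and gradient
   sparsification yield candidate click trains (three or more closely
   spaced peaks); a mel-spectrogram squeeze-and-excitation network confirms
   them, and dual microphones merge by logical OR.
6. **Scoring.** Events filtered by a duration threshold feed a composite
   scheme — wet-dog shake 1 point, head-raising 1, stereotypic 0.5, teeth
   chattering 2 per chatter-positive 5-min window — aggregated per animal
   and group, compared by unpaired t test (two groups) or one-way ANOVA +
   Tukey HSD.

A synthetic session generator (`session_spec()`, `synth_video_session()`,
`synth_audio()`) renders the whole rig — moving elliptical body, rhythmic
texture bursts, behavior glyph side views, click-train audio — with exact
ground truth, so every stage is tested without animal data.

## Worked example

```r
library(withdrawr)
library(dplyr)

spec <- session_spec(40, bind_rows(
  episode("wet_dog_shake", 5, 5.8),
  episode("rearing", 10, 14),
  episode("grooming", 20, 26),
  episode("teeth_chattering", 30, 30.5)), seed = 7)

ses <- synth_video_session(spec)
au  <- synth_audio(spec)

clip_model <- with(synth_clip_dataset(n_per_class = 30, seed = 0),
                   train_smoke(images, labels, variant = "cspm", seed = 0))

report <- run_pipeline(ses, audio = au, clip_model = clip_model)
report
#> Session analysis report
#>   frames discarded by motion filter: 68.5%
#>   side-stream fraction processed:    25.0%
#>   recognition-frame fraction:        7.87%
#>   segments: 3, events: 4, score: 4.5 (threshold 0 s)
#>   events by label: grooming=1, rearing=1, teeth_chattering=1, wet_dog_shake=1
```

The four scripted behaviors come back with their correct labels; the score
4.5 decomposes as rearing 1 + wet-dog shake 1 + grooming 0.5 + one
chatter-positive 5-min window 2. (This short demo session scripts motion in
~30% of its timeline, so the discarded fraction is below the >80% reached
on realistic sessions where motion occupies ~15%.) `autoplot()` methods
draw the motion signal with its segments and the per-group score cards;
`tidy()`/`glance()` tidy the group statistics.

A thin CLI over the same functions ships in `inst/cli/mwb.R`
(`simulate`, `analyze-video`, `analyze-audio`, `score`, `report`).

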