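---
title: "Personality-conditioned EEG emotion recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personality-conditioned EEG emotion recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Affective states are commonly described in Russell's circumplex: a valence
axis (pleasantness) and an arousal axis (activation), whose high/low
combinations define four quadrants — HV-HA, HV-LA, LV-HA, LV-LA. `eegaffect`
implements a two-branch deep pipeline for classifying these quadrants from
multichannel EEG while conditioning on the subject's Big Five personality
profile:

1. a **convolutional emotion branch** operating on short-time Fourier
   spectrogram images of 2-second EEG windows;
2. a **recurrent personality branch** (stacked LSTM) that reads sequences of
   those window features across a stimulation block and regresses the five
   IPIP-style trait scores (E, A, C, N, O);
3. a **fusion stage** that concatenates the branches' outputs (CNN part
   first) and feeds a final classical classifier — an RBF SVM by default,
   with MLP, kNN and naive Bayes alternatives.

The study population the package emulates comprises three screening groups —
Unstable Introvert, Unstable Extrovert and Normal — each viewing, per emotion
category (happy / sad / neutral), a block of 30 images sorted by ascending
arousal+valence rating and one closing video, while 32-channel 10–20 EEG is
recorded at 256 Hz.

## Preprocessing chain

`preprocess_chain()` applies, in order:

| stage | default | notes |
|---|---|---|
| decimation | 256 → 128 Hz | 8th-order low-pass at 0.8 × new Nyquist, zero phase, then keep every 2nd sample; event onsets rescaled and rounded |
| band-pass | Butterworth order 2, 0.4–60 Hz | applied forward–backward (zero phase) so event latencies are untouched |
| notch | 50 ± 2 Hz band-stop, order 2 | power-line suppression ≥ 90 % |
| ICA blink removal | threshold 0.8, seeded | see below |
| windowing | 2 s, 50 % overlap | 256 samples, 128-sample hop at 128 Hz; window labeled by the event covering its *start* sample; trailing partial windows dropped |
| baseline | first 200 ms | 200 ms × 128 Hz = 25.6 → rounded to 26 samples; idempotent by construction |

Zero-phase (forward–backward) filtering is a deliberate choice: the order-2
prototype is applied twice, so the magnitude response is the squared
Butterworth response, and group delay is zero — windows keep their alignment
with stimulus events.

**ICA artifact removal.** Manual visual inspection is not reproducible, so
the package replaces it with an automated rule: a seeded symmetric FastICA
(logcosh contrast, as many components as channels) decomposes the recording,
and any component whose time course correlates in absolute value above a
configurable threshold (default 0.8) with a frontal blink proxy — the mean
of the Fp*/AF* channels — is zeroed before back-projection. The decomposition
is deterministic given its seed, so the removal report is identical across
runs. This automated rule is a stand-in for operator judgment, not a claim
about the original procedure.

## Spectrogram features

Each window channel is transformed with a short-time Fourier transform
(frame, taper with a Hamming window *h*, transform, magnitude), cropped to
0.4–60 Hz, compressed with `log(1 + m)`, min–max scaled to [0, 1] and
bilinearly resized to the CNN input (32 × 32 by default). Two STFT presets
are supported because the natural parameterizations of a 2-s, 256-sample
segment differ: a *wide* preset (512-sample window, 256 step, zero-padded
input) giving one finely resolved spectral frame, and a *dense* preset
(128-sample window, 16 step) giving a 9-frame time–frequency image. The
pipeline default is the dense preset, which retains within-window temporal
structure; both remain config options, and no fixed output matrix size is
hard-coded — the image size is a configuration value.

**Multichannel aggregation.** How 32 channel spectrograms become one CNN
input is an open design point. The module supports `mean` (average
magnitude), `per_channel` (one image per channel) and `hemisphere` (a
2-plane image: left-hemisphere mean and right-hemisphere mean, midline
contributing to both). The *pipeline* default is `hemisphere`: averaging
magnitudes across all channels provably cancels any left/right-symmetric
power difference, and lateralized alpha power is exactly the kind of
valence-related structure this literature (and our generator) relies on.

## Network branches

**Emotion branch.** The reference backbone is VGG-16 — 13 convolutional
layers (3 × 3 kernels) in five max-pooled stages plus 3 fully connected
layers — and `build_cnn(backbone = "vgg16")` constructs exactly that
architecture for census and (optionally) materialized weights. Pretrained
weights are never downloaded; requesting them without supplying them is a
configuration error. Desk-scale work uses `small_cnn`, a four-block analogue
(8/16/32/64 filters, 3 × 3 conv + ReLU + 2 × 2 max-pool) whose flattened
last-stage activation (256 values at 32 × 32 input) is the feature vector.
The emotion head is a softmax classifier over those features trained with
Adam on cross-entropy (learning rate 0.001, batch 64); features are
standardized with training-split statistics only.

**Personality branch.** A stacked LSTM with layer widths 64/32/16; the first
two layers use ReLU cell activations, the third sigmoid, and a dense sigmoid
layer emits the five traits scaled to [0, 1]. Training minimizes mean
squared error with Adam and full backpropagation through time
(gradient-norm clipping at 5). Sequences are formed per subject and per
category block from the time-ordered window features (a stride subsamples
long blocks; the pipeline uses stride 8 on 1-second hops, i.e. one step per
8 s). Evaluation is leave-one-subject-out: each subject's traits are
predicted by the fold that held that subject out, and those held-out
predictions are what enters fusion — the fused classifier never sees a
subject's own trait fit. Because the branch is trained on MSE yet reported
with classification metrics, trait scores are binarized at the cohort median
per trait when such metrics are requested; the median split guarantees
balanced classes by construction.

**Fusion and the final stage.** The CNN part (features by default,
configurable to the 4 class scores) is concatenated before the 5 trait
outputs. The final-stage SVM uses an RBF kernel with cost and gamma chosen
by cross-validation strictly inside the training data (`train_final_classifier`
runs fully nested CV — an inner grid search inside each outer fold — and
`fit_final_classifier` runs the same inner search on a fixed training split).
MLP (single 16-unit hidden layer), kNN (k = 5, standardized features) and
naive Bayes are the documented alternatives.

## Evaluation conventions

Per-class one-vs-rest confusion counts TP/TN/FP/FN yield

- accuracy = 100·(TN+TP)/(TN+FN+TP+FP),
- precision = 100·TP/(TP+FP),
- recall = 100·TP/(TP+FN),
- F1 = 2PR/(P+R) computed from unrounded P and R,

reported rounded half-away-from-zero to two decimals; macro averages are
unweighted means over classes. Two conventions deserve emphasis. First, the
per-class "accuracy" uses the denominator exactly as the counts are given —
this is the convention of the reference tables the package reproduces, and
it is *not* the plain multiclass fraction-correct, which is exposed
separately as `overall_accuracy()` and used for all new experiments. Second,
metrics are scale-invariant in the counts, so percentage proportions and raw
counts are interchangeable. ROC curves are threshold sweeps of (FPR, TPR)
one class versus the rest; AUC uses the rank (Mann–Whitney) formulation with
ties counted as half-concordant. Splits are random stratified 70–15–15 with
largest-remainder integer allocation per stratum.

## The synthetic generator

The study's recordings are private, so the package ships a seeded generator
that emulates the protocol end to end. Per channel, the signal is a sum of
1/f background (spectrally shaped white noise, exponent 1), band-limited
theta (4–8 Hz), alpha (8–12 Hz) and beta (13–30 Hz) oscillations
(RMS 5/8/4 µV over a 10 µV background), white sensor noise (2 µV), and
raised-cosine blink templates (80 µV, 0.1/s) on frontal channels. Emotion
enters through two widely used heuristics — these are modeling choices to
give the pipeline learnable structure, not claims about the original data:

- **arousal → beta power**: beta amplitude is multiplied by √2 during
  high-arousal events and divided by it during low-arousal events
  (power ratio 2 by default);
- **valence → alpha asymmetry**: left/right alpha power ratio 1.5 during
  high-valence events, inverted for low valence.

Personality couples in through a global alpha-power gain,
1 + 0.8·(E − 3)/2 by default for extroversion. Stimulus ratings are drawn
from the published per-category distributions (images: happy 3.74 ± 1.05,
neutral 3.31 ± 0.94, sad 3.52 ± 1.17; videos: 3.38 ± 0.82 / 3.66 ± 0.91 /
2.72 ± 1.08) for the arousal axis, and from category-shifted normals
(5.4 / 4.0 / 2.6 ± 0.7) for valence, all truncated to the 1–7 rating scale.
Trait scores are truncated normals on the 1–5 item scale centred on the
cohort statistics, with the Unstable groups shifted up in neuroticism
(+1.2) and the extrovert/introvert groups shifted ±0.9 in extroversion.

**Quadrant thresholds.** Labels use a median-style split: arousal ≥ 3.5
(the median of the category rating mixture, which sits below the scale
midpoint) and valence ≥ 4. With these thresholds the four quadrants are
near-balanced (~25 % each), so 4-class chance is 25 % — the premise of every
chance-level control in the test suite. The same thresholds drive the
synthesis envelopes, so labels and physiology agree.

**Stimulus durations.** Images last 4 s and videos 60 s by default. The
image duration is not derivable from the protocol description (only the 2-s
analysis window is stated) and is therefore an explicit config value.

**What the generator does not model**: volume conduction and realistic
spatial covariance (channels are independent up to the shared envelopes),
non-stationary artifacts other than blinks, rating noise of human annotators,
and any true personality–EEG physiology. Passing the recovery tests
therefore demonstrates that the pipeline can extract the structure the
generator encodes — it says nothing about accuracy on real recordings, and
the reference study's headline numbers are not reproducible without its
private data.

## Numerical choices and problem sizes

- 200 ms baseline at 128 Hz rounds to 26 samples; fixed so tests are exact.
- ICA: components = channels, iteration cap 200 (40 in the pipeline profile),
  symmetric orthogonalization via SVD; the blink proxy is the frontal mean.
- LSTM: forget-gate bias initialized to 1, weights uniform-scaled by
  1/√(fan-in), gradient-norm clip 5, inputs z-scored with whole-set
  statistics, targets scaled to [0, 1] from the 1–5 item scale.
- Desk-scale profile (the package default): small_cnn backbone, 50 emotion
  epochs, 20 LSTM epochs, 6 subjects, full 30-image + video protocol;
  the final SVM trains on at most 1500 stratified-subsampled windows with a
  6-point inner grid. The full-scale profile (`paper_scale = TRUE`) restores
  500 epochs and the vgg16 backbone.
- Recovery studies used by the acceptance script: the strong-effect and
  null-effect runs use 6 subjects at the full stimulus protocol; the
  personality-recovery replicates use 6 subjects with 8 images per block, no
  video, hemisphere band-power features (log-scaled) and a 16/8/4 LSTM, 10
  seeded replicates. These sizes are the package's desk-scale choices and
  are stated here so results are interpretable.

## Known limitations

- The EDF writer targets interchange fidelity for this package's own
  round-trip (16-bit quantization, one annotations signal); it is not a
  general-purpose EDF+ implementation.
- The dense projection between fusion and the final classifier described in
  some variants of this architecture is intentionally omitted (direct
  concatenation → SVM); its width is not specified anywhere and the SVM
  performs the discriminative work.
- No statistical significance testing between classifiers is implemented;
  the comparison table reports point metrics only.
- `small_cnn` features are random-projection features (only the head is
  trained); this is sufficient for the synthetic structure and keeps the
  desk profile tractable, but fine-tuning the backbone would be required
  for real data.
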