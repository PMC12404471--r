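---
title: "Forecasting embryo development: models, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting embryo development: models, simulator and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(embryocast)
```

## The problem

In assisted reproduction, embryologists select embryos for uterine transfer
by watching time-lapse incubator videos: 8-bit grayscale frames of a single
embryo in a microwell, acquired every 7–20 minutes, annotated with
morphokinetic events (the times, in hours post insemination, at which the
embryo reaches the 2-cell, 3-cell, ... stages, compacts into a morula, and
forms a blastocyst). `embryocast` implements a forecasting system for such
videos: given the last two hours of development (a window of $F = 7$
frames), it predicts the next frame, and by feeding predictions back it
extrapolates development hours ahead — on day 2 across the cleavage stages
(31–43 hpi) and on day 4 from compaction to the start of the blastocyst
(90–113 hpi), for both clinically "transfer"-worthy and "avoid" embryos.

Clinical time-lapse videos are not redistributable, so the package is
exercised end-to-end on a bundled synthetic simulator (below) that
reproduces the *structure* of such data — geometry, annotations, frame
rates, study windows — without claiming photorealism.

## The frame predictor

A frame $x_i \in [0,1]^{H \times W \times C}$ stacks three identical image
channels with constant-valued auxiliary planes: normalized acquisition time
(min–max over the study window), and, for the cleavage study, the
annotated cell count divided by 9 (counts are annotated up to "9+"). Hence
$C = 5$ for the cleavage study and $C = 4$ for the blastocyst study, where
compaction makes counting impossible. Frames are bilinearly resized from
the native 250×250 to $H = W = 128$ at full scale.

The predictor $G_\Theta$ maps a window $X_{t-1,F} = [x_{t-F}, \dots,
x_{t-1}]$ to the next frame. It is a four-layer convolutional LSTM
(state-to-state transitions are convolutions; the standard peephole-free
cell) with 32/64/128/128 filters, kernels 7/5/3/1 and ReLU cell
activation. The first three layers return full sequences and are followed
by a normalization layer; the last returns only the final hidden state,
followed by dropout (rate 0.25). Two parallel convolution heads (kernel 3,
sigmoid) read that state: head 1 predicts the full $C$-channel frame (so it
can be fed back recursively), head 2 the 3-channel image on which all
quality metrics are computed. Training minimizes the sum of the two heads'
mean binary cross entropies (equal weights; the relative weighting is not
prescribed anywhere, and the sum is the simplest symmetric choice) with
Adam (learning rate $10^{-4}$, batch size 2; 50 epochs for the cleavage
study, 35 for the blastocyst study), and the checkpoint with the highest
validation accuracy of head 2 is kept. "Accuracy" for a sigmoid image head
is implemented as mean binary agreement at threshold 0.5 — the reading a
standard framework reports by default — with validation loss available as
an alternative selection metric.

Two implementation choices deserve explanation:

* **Normalization.** The package trains with gradient accumulation at
  batch size 2 on one CPU, so batch statistics would be noisy and would
  couple inference to batch composition. The normalization after the first
  three ConvLSTM layers therefore computes per-sample, per-timestep channel
  statistics over the spatial plane (instance-normalization style) with
  learned gain and shift. Inference is exactly batch-independent and needs
  no running-statistics state.
* **Compute core.** No deep-learning framework is part of the package's
  dependency footprint: convolutions (im2col + GEMM), the ConvLSTM
  recurrence, the U-Net, backpropagation and Adam are implemented in
  C++/RcppArmadillo inside the package and verified against finite
  differences in the test suite (`test-nn-core.R`).

### Scale presets

The `"paper"` preset above is faithful but sized for GPU training. The
`"tiny"` preset — ConvLSTM filters 4/8/16/16, kernels unchanged, 64×64
frames — is what the test suite and the acceptance script train: one
gradient step costs ≈0.6 s on a single CPU, so a few hundred to a couple of
thousand steps fit in a desk-scale run. This is the package's own choice of
test scale; with wider layers (8/16/32/32) a step costs ≈3 s, which buys
too few optimization steps to be useful in the same wall-clock budget.

## Recursive forecasting

Both strategies slide the window one frame at a time and append head-1
output as the next input:

* **Forecast till the end** starts from the first $F$ real frames and rolls
  to the end of the study; the prediction for frame $t$ has horizon
  $t - F$, and from the second step onward the window contains predicted
  frames.
* **Forecast the next 7 frames** predicts horizons 1–7 from the latest
  *real* window; when the next real frame arrives, the window advances
  using real frames only and all seven forecasts are recomputed (each
  overlapping label is superseded; one new farthest label appears). The
  "pause until the next frame" of a live incubator is modeled as an
  event-driven iterator — wall-clock waiting is out of scope.

During recursion the time plane of a fed-back frame is overwritten with the
true normalized acquisition time — the acquisition schedule of an incubator
is known a priori, so this uses no information unavailable at forecast
time — and the predicted cell-count plane is collapsed to its spatial mean
so it remains a constant-valued channel. Whether the original system fed
auxiliary channels back raw is not documented; both modes exist behind the
`feedback` argument, with the schedule-overwrite mode as default. Predicted
images are clipped to $[0,1]$ before re-ingestion (a no-op after a sigmoid;
kept as a safety net).

## The embryo cropper

Forecast quality is dominated visually by the static microwell background,
so evaluation also runs on background-free frames. A vanilla U-Net
(two-convolution blocks, four pooling levels at full scale, skip
connections, softmax over embryo/background, sparse categorical cross
entropy; Adam $10^{-3}$, batch 32, 60 epochs, horizontal+vertical flip
augmentation applied identically to image and mask, 80:20 split) predicts
the embryo mask. Two classes are the minimal reading of
"embryo vs background" segmentation. Predicted masks are cleaned to their
largest connected component — an embryoslide well contains one embryo — a
step that can only shrink the foreground. The mask predicted from a
ground-truth frame is matted (background zeroed, optional Gaussian-feathered
alpha, default hard) onto both the ground-truth frame and the paired
predicted frame; transformer-based soft matting of the original system is
an external pretrained component and is deliberately replaced by this
binary matte, which preserves the evaluation contract (background removal
before metrics).

On the synthetic data the renderer supplies exact masks, emulating the
hand-annotated mask dataset of a clinical setup.

## Quality metrics

* **PSNR** $= 10\log_{10}(1/\mathrm{MSE})$ at data range 1, capped at
  100 dB for the zero-error case so averages stay finite.
* **SSIM** with Gaussian weighting ($\sigma = 1.5$, 11-tap window,
  $K_1 = 0.01$, $K_2 = 0.03$), plain weighted moments, edge-cropped mean —
  verified in the tests to agree with scikit-image's
  `structural_similarity` to $10^{-6}$ on random images.
* **FVD-style distance.** The Fréchet distance
  $\lVert\mu_1-\mu_2\rVert^2 + \mathrm{Tr}(\Sigma_1 + \Sigma_2 -
  2(\Sigma_1\Sigma_2)^{1/2})$ between Gaussian fits of spatio-temporal
  sequence features, computed with the symmetrized PSD square root and a
  small diagonal jitter. The canonical choice of feature extractor is a
  pretrained 3-D video network; no such checkpoint can ship here, so the
  default embedder is a *seeded deterministic* one: grayscale reduction,
  16×16 bilinear downsampling, temporal differencing, a fixed random bank
  of 3×3×3 filters with ReLU and pooled statistics, then a seeded random
  projection to the requested dimension. It is deterministic given the
  spec, sensitive to temporal order, and zero for identical sets — the
  properties the evaluation relies on. Absolute values are **not**
  comparable across embedders (nor to published tables computed with
  pretrained features); only orderings and trends within one embedder are
  meaningful. `embedder_spec(fn = ...)` accepts an external embedder.

Sequences are truncated before embedding: 10/14/28 frames for the cleavage
study and 60/120/180 for the blastocyst study. Each evaluated video
contributes one sequence per side, so an FVD needs at least two videos.

## The synthetic simulator

`simulate_video()` renders, at every acquisition time on the half-open grid
$[t_0, t_1)$ with spacing $1/\text{fph}$ (so duration × rate frames
exactly), a deterministic scene: a textured microwell floor (≈45) with a
well ring (≈90), a zona pellucida annulus (≈120) around a perivitelline
space (≈95), and $k$ shaded blastomere discs (cytoplasm ≈170, membrane
≈220) for the stage active at that time, packed so that for $k \le 4$ the
thresholded components never touch (the annotation-consistency oracle in
the tests counts components and compares to the annotated cell count).
Compaction and morula render as a single bumpy blob; blastocyst stages add
an expanding dark cavity, a bright trophectoderm band and optionally an
inner-cell-mass blob.

Morphokinetic schedules are drawn per category: "transfer" division times
come from tight distributions around typical timings (t3 ≈ 36 hpi, morula
≈ 97 hpi, ...); "avoid" schedules draw delayed intervals or arrest
entirely (probability 0.3 cleavage / 0.35 blastocyst) and carry more
fragmentation. These distributions are *placeholders with realistic
centers*, exposed in `sim_config()` — no clinical dataset was fit.

Real time-lapse footage is never static between events, and a renderer that
were piecewise-constant would make the copy-last-frame persistence baseline
unbeatable by construction; the simulator therefore includes the continuous
dynamics real videos show: slow embryo rotation (ω ~ N(6, 2)°/h), brief
post-division settling (cells relax from 1.06× over 30 min), continuous
blastocoel expansion, fragment drift, per-frame sensor noise (σ = 4 of 255)
and LED illumination flicker (gain σ = 0.8%). All of it is a deterministic
function of (config seed, time), so identical configs give byte-identical
videos. These values were fixed once, on plausibility grounds, when the
simulator was written.

What passing tests on this simulator do and do not show: they validate the
*mechanics* — tensor contracts, index bookkeeping, learnability of smooth
deterministic dynamics, segmentation of a high-contrast foreground, metric
behavior — not clinical image quality. Real Hoffman-contrast embryo
footage has texture, focus drift and optical artifacts the simulator does
not attempt; absolute metric values on synthetic data say nothing about
performance on clinical data.

## Numerical choices and degenerate inputs

* Convolutions: odd kernels, same zero padding; bilinear resizing
  everywhere (tie-free).
* BCE probabilities clamped to $[10^{-7}, 1-10^{-7}]$ inside the loss;
  softmax log-probabilities floored at $10^{-12}$.
* Fréchet: eigenvalues clamped at 0 before square roots; result floored at
  0; covariance jitter $10^{-10}$.
* Degenerate configs (windows shorter than one frame interval, split
  ratios outside (0,1), fragmentation above 15%, non-divisible U-Net
  sizes, mismatched shapes) fail fast with explicit errors; videos shorter
  than $F+1$ frames yield empty pair lists rather than errors.
* Frame labels are 1-based in all reports and provenance tables, matching
  the $x_1 \dots x_N$ convention; internal array indexing is R's native
  1-based indexing throughout.
* Seeding: every stochastic component (schedules, geometry, noise, weight
  init, shuffling, dropout, flips, embedder) derives from explicit seeds
  via a scoped-RNG helper, so runs are reproducible and the global RNG
  stream is never disturbed.

## Problem sizes used in the shipped runs

The test suite and the acceptance script train the tiny preset on 20
cleavage-stage videos (16 train / 4 validation) at 64×64 with a capped
number of gradient steps, evaluate one-step error on 4 further held-out
videos against the persistence baseline, train a depth-2, base-8 U-Net for
10 epochs on renderer-supplied masks, and run the end-to-end pipeline on a
6-video cohort. These sizes are the package's chosen desk-scale operating
point; the `"paper"` preset and full-scale training configurations remain
available for hardware that can afford them.

## Known limitations

* The tiny preset under a desk-scale step budget produces visibly blurred
  predictions; sharpness comparable to the persistence baseline requires
  either many more optimization steps or the full-scale architecture.
* The default FVD embedder is not a pretrained perceptual network; its
  absolute scores are package-internal.
* The simulator does not model multiple focal planes, Hoffman-contrast
  optics, or visual degeneration of arrested embryos beyond timing and
  fragmentation.
* Transfer/avoid is a property of the generator, not a classifier output:
  the package forecasts morphology and leaves the clinical decision out of
  scope.
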