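---
title: "Coarse-to-fine U-Net cascade for pupil and iris segmentation: models and methods"
author: "oculocascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine U-Net cascade for pupil and iris segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During ocular proton therapy the patient fixates a light so that the treated
eye holds a planned gaze angle, while an eye-tracking camera records close-up
infrared video of the eye surface (512 x 640 frames). Monitoring gaze
stability requires knowing, frame by frame, where the pupil and iris are.
`oculocascade` implements a fully automatic two-stage segmentation:

1. **Eye localisation.** A U-Net sees the whole frame (down-scaled to the
   network input) and predicts the merged iris-and-pupil region. Its
   binarised output yields the eye centre, around which a 350 x 350 region
   of interest (ROI) is cropped.
2. **Fine segmentation.** Two further U-Nets, one for the iris and one for
   the pupil, segment their structure inside the ROI. Their masks are
   post-processed, resized back to the window, and pasted into full-frame
   coordinates.

Cropping first buys the fine networks roughly a four-fold higher resolution
on the anatomy and removes background structures (eyelids, retractors,
skin), which is why the cascade outperforms a single full-frame network.

## Synthetic phantoms instead of clinical video

Clinical recordings of this kind are not publicly available, so the package
ships a phantom generator ([samplePhantomScene()]) whose defaults define the
study conditions used throughout the tests:

* frame 512 x 640, eye centre jittered up to ±120 px per axis from the frame
  centre (so partially out-of-frame eyes occur, exercising the window
  clamping);
* iris radius uniform in [90, 140] px, pupil radius a uniform fraction
  [0.25, 0.55] of the iris radius — the pupil is strictly smaller by
  construction;
* nominal gray levels 30 (pupil), 110 (iris), 210 (sclera) on the 0–255
  scale, matching the dark-pupil appearance of infrared illumination;
* occluders: an upper eyelid arc (probability 0.7), a lower arc (0.4), a
  bright retractor band along the upper lid margin (0.3), all drawn over
  the eye *after* the ground truth is fixed;
* 0–3 specular glints (bright disks, radius 2–6 px) inside the iris area;
* a multiplicative linear illumination gradient with slopes in ±0.25 per
  half-frame, Gaussian blur with sigma in [0.5, 2] px, and additive Gaussian
  noise with sigma in [2, 8] gray values, clamped to 0–255.

Ground truth is the *clean analytic geometry*: pixels whose centres lie
inside the pupil or iris circle (centre-sampling rasterisation, a
deterministic and oracle-checkable rule). The iris truth is the full
limbus-bounded disk, pupil included, so the localisation target (iris u
pupil) coincides with the iris disk and the two structures are evaluated
independently. Occluders alter only the image: an annotator outlines the
full anatomical contour even under a partially closed lid, and keeping the
truth analytic makes every geometric test exact.

**What the phantoms do not emulate:** real iris texture and limbus softness,
eyelash detail, radio-opaque marker shadows, camera vignetting and motion
blur, and any temporal correlation between frames (scenes are i.i.d.).
Phantoms are higher-contrast than clinical frames, so passing the phantom
study shows the *pipeline* is correct and trainable; it does not certify
clinical-grade accuracy, and the reference clinical medians are therefore
used as lower bounds rather than as values to match.

## Architecture

All three networks share one U-Net: per resolution level two 3 x 3 "same"
convolutions, each followed by batch normalisation (conv → norm →
activation) and a leaky ReLU; 2 x 2 max-pooling between encoder levels;
feature maps double per level (base 16 → 256 at depth 5); the decoder
doubles the grid, concatenates the encoder skip of the same level, and
halves the feature maps; a 1 x 1 convolution with a sigmoid produces a
single-channel probability map the size of the input (256 x 256 by
default).

Three details are not fixed by a block-level description, and the package
treats them as an explicit, configurable variant space:

* **Decoder mode.** `upconv_concat` (default): a learned 2 x 2
  up-convolution that halves the feature maps before concatenation;
  `upsample_concat`: parameter-free nearest-neighbour up-sampling, which
  leaves more channels at the concatenation.
* **Normalisation accounting.** Each batch-norm layer carries two optimised
  scalars per channel (scale, shift) and two moving statistics (mean,
  variance). Framework summaries of the era counted all four in the
  headline total; `countTrainableParams()` follows that convention by
  default and exposes `includeNormStats = FALSE` for the strict count.
* **Leaky-ReLU slope.** Not determined by the design; the default 0.3 is
  the historical default of the frameworks this architecture family grew up
  in, and it is configurable.

Under the defaults the reference architecture (base 16, depth 5,
256 x 256 x 1) totals **1,947,665** parameters — 1,944,241 optimised scalars
plus 3,424 moving statistics. This is the configuration, selected from the
variant space above, that comes closest to the reference total of 1,947,153
quoted for this architecture; the residual difference of 512 (+0.026%)
could not be closed by any principled member of the space (the nearest
decompositions would require dropping the normalisation of exactly one
128-channel layer, which we declined as arbitrary). The pinned count and
the closed-form layer summation are both asserted in the test suite.

## Training recipe

* **Initialisation** (not fixed by the design, so a package choice):
  He-normal convolution kernels, zero biases, unit/zero batch-norm scale
  and shift — except the sigmoid head's bias, which starts at the logit of
  a 10% foreground prior (≈ −2.2). The pupil, iris and merged-eye masks
  all cover small image fractions; starting from an under-segmenting state
  instead of p = 0.5 everywhere removes the long initial phase in which
  cross-entropy training merely pushes the background down, and aligns
  the untrained state with the cascade's deliberately low thresholds.
  This matters at desk scale, where the step budget is a small fraction of
  the full recipe's.
* Adam with constant learning rate 1e-4 and zero decay (moments 0.9/0.999,
  epsilon 1e-7 — framework defaults, as they are not otherwise determined),
  batch size 4, pixel-wise binary cross-entropy, 60 epochs at full scale.
* **Checkpointing:** after each epoch the mean training cross-entropy is
  compared with the best so far; the returned weights are those of the best
  epoch. Selection is on the *training* set — `trainNetwork()` logs a note
  recommending a held-out split, but mirrors the recipe faithfully.
* **Augmentation**, sampled per pair and epoch and applied identically to
  image (bilinear) and mask (nearest-neighbour, so binarity is preserved):
  independent horizontal and vertical reflections with probability 0.5
  each; clockwise rotation uniform in [0, 360) degrees about the image
  centre; integer translation per axis uniform in [−70, 70] px (the stated
  0–70 range is read as a magnitude, with the sign sampled — reflections
  already cover the symmetry); zoom uniform in [0.8, 1.2] about the centre
  (a ±0.2 factor). Out-of-canvas regions are filled with 0.
* **Accuracy** in the history is pixel-wise binary accuracy at threshold
  0.5 — the natural reading for a per-pixel sigmoid head.

The engine itself (convolutions, transposed convolutions, pooling, batch
normalisation, the warps and the Adam loop) is implemented in single
precision in C++ on top of the linked BLAS. Every random draw —
initialisation, shuffling, augmentation — comes from R's RNG, so a single
`set.seed()` (or the `seed` fields of the configuration objects) makes
training bit-reproducible on a fixed platform. The training-history
invariant tests rely on this.

## Cascade inference

Fixed pipeline order (see `runCascade()`): resize frame bilinearly to the
network input → localisation map → **threshold** (strict `>`, 0.2) →
**morphological closing** (disk radius 5 at network resolution) →
**largest 8-connected component** → nearest-neighbour up-scaling of the
*binary* mask to full frame → centroid (rounded half-up) → 350 x 350 window
clamped by minimal translation into the frame → ROI crop → resize to the
network input → iris network (threshold 0.5), then pupil network
(threshold 0.15) → closing + largest component each → nearest-neighbour
resize to the window → paste-back.

Choices worth making explicit:

* Binarise **then** rescale, with nearest-neighbour interpolation for all
  mask resizes: masks stay exactly binary through the whole pipeline, and
  the nearest rule (output pixel k reads input pixel `floor((k+0.5)·n/m)`)
  makes down-up round trips on block-constant masks exactly invertible.
* The closing element size is not determined by the design; a disk of
  radius 5 on the 256 grid is the default and is exposed in
  `CascadeConfig`.
* The low pupil threshold (0.15) deliberately trades a slight
  over-segmentation for robustness of the small, dark structure; the ROI
  threshold (0.2) similarly favours recall, because the later stages only
  need a good window, not a good mask.
* Equal-size component ties are broken towards the component whose minimal
  (row, col) pixel is lexicographically smallest — irrelevant in practice,
  but it makes the operation a function.
* Degenerate predictions are **flags, not exceptions**: an empty
  localisation mask falls back to a frame-centred window (`roi_empty`), an
  empty fine mask yields an empty full-frame mask (`iris_empty` /
  `pupil_empty`), and clamping is recorded as `window_translated`. Batch
  video processing must never abort mid-run.
* Window coordinates are 0-based and half-open everywhere; centroids round
  half-up. For video streams where the eye position is stable,
  `runCascade(..., roiBox = )` freezes the window and skips the
  localisation stage; per-frame localisation remains the default.

## Metrics

Dice `2|A∩G|/(|A|+|G|)`, Szymkiewicz–Simpson `|A∩G|/min(|A|,|G|)`, IoU
`|A∩G|/|A∪G|`, and the symmetric Hausdorff distance between **contours**
(a contour pixel has at least one 4-neighbour outside the mask;
out-of-grid counts as outside) — the "maximum contour distance" reading;
using all mask pixels instead would only shrink the distance for nested
masks. The eye-centre error is the Euclidean distance between the
*unrounded* centroid of the localisation mask and the reference centre.

All metrics are computed on **full-frame masks after paste-back**, so ROI
mislocalisation penalises the fine scores. Summaries report median and
quartiles with R's default linear-interpolation quantile rule (type 7).
Empty-mask cases yield an `NA` sentinel rather than an imputed 0: they are
excluded from the statistics but counted and reported (`n_undefined`), so
failure analysis stays explicit.

## Problem sizes used in the shipped studies

The test suite and the acceptance script run a scaled-down version of the
full study, chosen once as the package's standard desk-scale configuration
(`runScaledExperiment()`): 300 training phantoms, 60 held-out phantoms,
all three networks at base 8 filters, depth 5, 128 x 128 input, 12 epochs
of the recipe above with the translation bound scaled with the input
(70 · 128/256 = 35 px). At this scale the iris scores and the eye-centre
error reach the package's validated bounds, while the pupil scores remain
resolution-limited: the low 0.15 threshold captures the finite-width
probability transition around the blurred pupil boundary, a systematic
~1 net-pixel dilation that only a several-fold larger step budget or a
finer input grid sharpens away (the pupil net is confident — its failure
mode is a thin halo, not mislocalisation). The geometric pipeline
identity is additionally
checked with oracle probability maps (exact ground truth fed through the
cascade) over 100 phantoms, where the only loss is resize quantisation.
Metric kernels are validated against brute-force oracles on ~1,000 random
mask pairs.

## Known limitations

* No AVI decoding is bundled: frames are read from PNG/TIFF directories
  (extract video frames with an external tool first). This keeps the
  package free of codec dependencies.
* Inference-time benchmarking is informational only; no timing is part of
  the validated surface.
* The phantom generator renders i.i.d. frames; temporal behaviour
  (tracking stability, smoothing) is out of scope.
* Training runs single-threaded on the CPU; the engine is sized for the
  desk-scale studies above, not for full-scale (256², base 16, 60-epoch)
  training, which is possible but slow.
* Bit-level reproducibility holds for a fixed platform/BLAS; across
  platforms expect agreement only to float tolerance.
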