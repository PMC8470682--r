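---
title: "Grayscale polyp detection and classification: models and methods"
author: "polypgray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grayscale polyp detection and classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polypgray)
```

## The problem

Colorectal polyps are found and optically diagnosed during colonoscopy.
Two machine tasks matter clinically: *detection* (is there a polyp in
this frame, and where) and *classification* (is the polyp neoplastic —
adenoma or invasive cancer, requiring resection — or hyperplastic,
which may be left in place under a diagnose-and-leave policy if the
negative predictive value of the classifier is at least 90%).
`polypgray` implements a lightweight, fully tabulated convolutional
pipeline for both tasks that operates on *grayscale* (luma-converted)
frames, together with the complete evaluation and statistics layer used
to compare a grayscale arm against a color arm on the same images.

## Preprocessing

Color frames are converted to a single luma channel as
`gray = 0.299 R + 0.587 G + 0.114 B` (ITU-R BT.601), rounded
half-away-from-zero and clipped to 0–255.  A second, selectable
coefficient set (0.229, 0.587, 0.117) reproduces a variant that appears
in parts of the applied literature; its weights sum to 0.933, so pure
white maps to 238 rather than 255.  The standard set is the default
because channel-constant pixels should be fixed points of the
conversion; the variant exists for fidelity reruns
(`rgb_to_grayscale(img, "paper")`).  Whether published grayscale runs
rounded or truncated is not stated anywhere we know of; we round, and
the choice is isolated in one quantizer.

Ground truth arrives either as box tables or as binary masks
(CVC-Clinic style).  Masks are converted with an 8-connected component
search whose boxes are the tight min/max row/column extents — the
boundaries of the white region become the four sides of the box.
8-connectivity is chosen because annotated lesion blobs are solid:
4- versus 8-connectivity differs only at diagonal touching, and a
clinician who drew two diagonally touching strokes meant one lesion.
Coordinates are 0-based, top-left origin, half-open; the source material
never states a convention, so the least ambiguous one is pinned and
tested.

## The detection network

The detector consumes a 128 × 128 input (1 channel for grayscale, 3 for
color).  Each convolution block applies three parallel same-padded
kernels per filter — 3 × 3, 3 × 1 and 1 × 3 — whose responses are
summed elementwise, followed by batch normalization (ε = 10⁻⁵), ReLU,
and (in the first three blocks) 2 × 2 stride-2 max pooling:

| stage | filters | output |
|---|---|---|
| input | – | 128 × 128 |
| MK-conv + BN + ReLU + pool | 16 | 64 × 64 |
| MK-conv + BN + ReLU + pool | 32 | 32 × 32 |
| MK-conv + BN + ReLU + pool | 64 | 16 × 16 |
| MK-conv + BN + ReLU (×3) | 128 | 16 × 16 |
| 1 × 1 conv head | 24 | 16 × 16 |

The elementwise *sum* of the three kernels is an interpretation: the
tabulated per-block output channel count equals a single filter count,
which rules out plain concatenation.  Summation is also what makes the
block collapse algebraically into one effective 3 × 3 kernel (the 3 × 1
embedded in the middle column, the 1 × 3 in the middle row), which is
how the implementation computes it — one im2col and one BLAS `gemm` per
block.  A concatenate-then-1 × 1-project variant is available behind
`combine = "project"` for anyone exploring the alternative reading.

The printed convolution equation indexes the kernel in flipped
(convolution) order; the implementation, like mainstream deep-learning
frameworks, computes the unflipped sliding-window correlation.  For
learned kernels the two parameterizations are equivalent up to a
relabeling of weights, and the test oracles pin the implemented
semantics.

### Anchor-grid decoding

The 24 head channels are read as 8 anchors × (objectness, x-offset,
y-offset) — the anchor shapes, in original-frame pixels, are (16,16),
(32,32), (24,48), (48,24), (60,80), (108,72), (216,144), (180,180).
The per-anchor channel semantics are not stated in the source material;
this 3-tuple reading is the smallest one consistent with 24 channels
and 8 printed anchors, and it is recorded as an interpretation.  Since
anchors up to 216 px cannot fit the 128 × 128 network input, anchors
live in the original frame and cell (r, c) of the 16 × 16 grid maps to
the frame through the cell stride (W/16, H/16):

* center_x = (c + sigmoid(tx)) · W/16
* center_y = (r + sigmoid(ty)) · H/16
* box width/height = the anchor's dimensions, clipped to the frame.

Sigmoid offsets confine each center to its own cell, the standard
grid-detector convention.  Detections keep every anchor whose sigmoid
objectness clears the cutoff (operating point 0.2), sorted by score;
greedy overlap suppression at IoU 0.5 is on by default and can be
disabled, since the source is silent on duplicate boxes.

### Training targets and loss

For each ground-truth box, the cell containing its center is positive
for the single anchor with the best shape IoU (computed co-centered;
ties to the lowest index); offset targets are the center's fractional
position in the cell.  The loss is binary cross-entropy on objectness
plus squared error on the sigmoid offsets over positives.  Positive and
negative slots are normalized *separately* (positives weighted
`pos_weight`, default 1): a 16 × 16 × 8 grid holds ~2000 negative slots
per positive, and a jointly normalized mean would leave the positives
with a vanishing share of the gradient.  The head's objectness biases
are initialized to −4 so the untrained detector is silent and early
updates concentrate on the positives.  None of the training recipe is
stated in the source; everything (Adam, learning rate 10⁻³,
accumulation batch 2, epochs) lives in `detector_config()`, not in
code.

## The classification network

The classifier consumes a 480 × 640 (H × W) frame and emits two softmax
classes.  Six multi-kernel blocks (16, 16, 32, 32, 64, 64 filters) are
pooled at strides 2, 2, 3, 3, 3; the tabulated final pooling row reads
"2 × 2/1" but 4 × 6 → 2 × 3 is only achievable at stride 2, so stride 2
is implemented and the discrepancy documented — the printed output
shape is treated as binding.  A frame is called neoplastic when its
neoplastic softmax probability is ≥ 0.5; a tie at exactly 0.5 resolves
to neoplastic, the clinically conservative direction (it favors
resection review over leave-in-place).  Class imbalance is handled by
inverse-frequency loss weights, configurable.

Whether classification consumed full frames or detector crops is an
open question in the source ("the detected polyps were subsequently
classified", with no crop geometry).  Full resized frames are the
default; `classifier_config(crop = TRUE)` classifies a margin-expanded
crop around the (detected or ground-truth) box instead, which is the
mode the end-to-end synthetic protocol uses — it matches the
detection-then-classification reading and makes the texture, not the
scene, carry the decision.

### Batch-normalization statistics

Normalization statistics are computed per channel over the spatial
positions of the image being processed (the optimizer still sees an
effective minibatch through gradient accumulation).  With the deep
surrounds of a 128-unit block this behaves like instance normalization;
it keeps training and inference bit-identical (no running-average
state) and sidesteps stale-statistics artifacts in short training runs.
The general `batch_norm_forward(values, mu, sigma2, gamma, beta, eps)`
primitive with caller-supplied statistics is exported unchanged.

## Evaluation layer

Detection is scored by the center-point criterion of the MICCAI
endoscopic-vision challenge: a prediction is a true positive iff its
box center falls inside (edges inclusive) a ground-truth box; a false
negative is scored once per image when no box appears at all.  True
negatives are undefined for box matching.  A per-ground-truth FN mode
exists for multi-polyp frames, since the image-level definition is
ambiguous there; the image-level rule (at least one TP and a box
present) is the default.

Image-level detection accuracy is correct polyp images over total polyp
images; for normal frames "correct" means zero detections (reported
separately as specificity).  The classification panel is accuracy
(TP+TN)/total, precision, recall, F1 = 2PR/(P+R) and the recall-heavy
F2 = 5PR/(4P+R), reported as percentages at one decimal.  (The source's
metric table prints accuracy as (TP+FN)/total, but its own reported
values are only consistent with (TP+TN)/total — e.g. (118+31)/180 =
82.8% — so the standard formula is implemented and the printed variant
treated as a typo.)  NPV = TN/(TN+FN) is reported at integer precision,
as is clinical convention, and the pixel-area stratifier re-derives it
after excluding lesions below a threshold (1600 px ≈ 40 × 40, and 1800
px, are the operating points of interest; a 40 × 40 box belongs to the
upper stratum).

Paired arms on the same images are compared with the *exact* McNemar
test — two-sided binomial on the discordant counts,
p = min(1, 2·P(X ≤ min(a,b))), X ~ Binomial(a+b, ½) — because
discordant counts in these comparisons are tiny (0–19), where the χ²
approximation is invalid.  Proportions get Clopper–Pearson intervals
(beta-quantile form); the Wilson interval is available as an option,
but Clopper–Pearson is the default because it reproduces the published
intervals exactly at one decimal where Wilson does not (843/900 upper
endpoint).  AUC uses the rank (Mann–Whitney) formulation with ties
counted one half.

## The synthetic scene generator

No clinical images ship with the package; every pipeline is exercised
on generated 640 × 480 colonoscopy-like frames: a radially vignetted
lumen, sinusoidal-plus-smoothed-noise wall wrinkles, a handful of
specular highlights, and additive sensor noise, in a white-light-like
(warm pink) or narrow-band-like (red-suppressed, green/blue-boosted)
palette.  Polyps are elliptical protrusions — a cosine dome with a
darker rim — carrying one of two textures that mirror the optical
taxonomy: dark tubular/branched vessel strokes (neoplastic-like) or
light uniform dots (hyperplastic-like).  Semi-axes are solved from the
requested tight-box area, so datasets can straddle the 1600- and
1800-pixel thresholds exactly; the rendered box stays within 10% of the
target.  Everything derives from one integer seed, byte for byte.

The generator exists to exercise code paths, the size-threshold
analyses and the paired statistics — not to mimic hemoglobin optics,
motion blur, stool, or the long-tailed difficulty of real endoscopy.
Passing synthetic bars therefore demonstrates that the machinery
learns, decodes and scores correctly; it says nothing about clinical
accuracy, and the published real-data figures (95.1% pooled grayscale
detection, 82.8% NBI classification accuracy, AUC 0.93) are not
reproducible without the hospital images.

## The end-to-end protocol and its problem sizes

`run_experiment()` wires the stages into the published protocol shape:
split (holdout by default; 5-fold `make_folds()` optionally), per-arm
detector training, center-point evaluation with exact CIs, crop-mode
classification on the grayscale arm (the published optical-diagnosis
tables are grayscale), area-stratified reruns, and the paired exact
McNemar test between arms.  Reports embed the master seed and an
FNV-1a hash of the configuration; rerunning a report's config
reproduces it bit for bit.

The default study conditions — 400 frames (≈300 polyp / 100 normal),
75/25 holdout, detector 10 epochs (grayscale) and 1 epoch (color arm,
which only needs to complete for the paired comparison), classifier 2
epochs on a 120-frame balanced subset — were chosen once as a size a
single CPU handles in minutes while leaving the grayscale detector
enough updates (~1500) to converge on the synthetic task.  The
acceptance script runs the same protocol at 240 frames.

## Numerical choices and degenerate inputs

* Quantization: round-half-away-from-zero everywhere an 8-bit value is
  produced; bilinear resampling uses the pixel-center
  (align-corners-false) convention, clamped at borders.
* Convolution accumulates in double precision; oracle agreement is
  required to 10⁻⁵ in tests, far above accumulation error at these
  sizes.
* BN variance is biased (divide by N), floored by ε = 10⁻⁵.
* A tie in the best-anchor IoU resolves to the lowest anchor index; a
  prediction center exactly on a ground-truth edge counts as inside; a
  classification tie at exactly 0.5 is neoplastic.
* Degenerate inputs fail loudly: empty datasets, single-class training
  sets, all-zero confusion matrices, zero-contrast polyps, polyps
  crossing the frame edge, pooling windows larger than their input.

## Known limitations

* The per-anchor head encoding, kernel-combination rule, loss and
  training recipe are documented interpretations of an under-specified
  source; alternatives (projection combine, per-GT FN counting, Wilson
  intervals, full-frame classification) are switchable, not silently
  chosen.
* Anchor dimensions are never refined by regression — boxes inherit
  their anchor's size, so box *extent* accuracy is limited to the
  anchor inventory even though the center criterion is unaffected.
* Instance-style BN statistics deviate from cross-image batch
  statistics; at these network widths the practical effect is small,
  and determinism was judged worth more than fidelity to an unstated
  batch size.
* The generator's two palettes are stylized; no attempt is made at
  NBI spectral fidelity, and negatives reuse the background generator
  unchanged.
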