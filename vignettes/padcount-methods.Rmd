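---
title: "Counting mosquitoes on an observation pad: models, design choices and limits"
author: "padcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting mosquitoes on an observation pad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(padcount)
```

## The problem

A mosquito surveillance station lures adult mosquitoes onto a plain white
observation pad and photographs it at intervals. Two questions follow from
each image: *how many mosquitoes are on the pad right now*, and -- from the
count time series -- *is this site an active breeding habitat*, in which
case a larvicide package should be released into the nearby static water.
`padcount` implements the full image-analysis chain for such a station, in
two competing flavours:

* a **per-contour baseline**: threshold dark objects, crop each contour to a
  60×60 patch, classify every patch with a small CNN, and count the
  accepted contours (one network inference per contour);
* a **score-map regression pipeline**: a fully convolutional network (FCN)
  produces a coarse per-pixel class-score map; the map taken *before* the
  final upsampling is converted to an image and fed to a second CNN that
  regresses the mosquito count directly (exactly two network inferences per
  image, independent of how many insects are present).

The FCN's training labels are not drawn by hand: the patch classifier is run
over all detected contours, and accepted contours are painted purple
(255, 0, 255) on a black canvas. This weak-label bootstrapping is the core
idea: a cheap patch-level annotation effort is promoted into pixel-level
supervision, and the FCN is only asked for *rough localisation*, not exact
outlines, which keeps the number of required training images low (about one
hundred).

## Networks

Two architectures are provided by `buildNetwork()`:

* an AlexNet-style network (five convolutions, 2 filter groups in
  conv2/4/5, LRN after conv1 and conv2, three fully connected layers,
  dropout 0.5), used both as the 2-class patch classifier and -- with the
  final layer replaced by a single scalar output trained with Euclidean
  distance loss -- as the count regressor;
* a VGG-16-backbone FCN: 3×3 convolution blocks of 2/2/3/3/3, ceil-mode 2×2
  pooling, fc6 as a 7×7 convolution to 4096 channels, fc7 1×1, a 1×1
  scoring layer, a 2× upsampling deconvolution, a pool4 skip fusion
  (1×1 score, centre crop, element-wise sum) and a final 16× upsampling
  deconvolution. Deconvolutions are full (not per-class grouped) and
  bias-free.

At `widthScale = 1` the layer shape table reproduces the reference designs
exactly, including the parameter totals (134.82 M for the FCN with a
21-channel head, 60.97 M for AlexNet with its original 1000-way head);
`countParameters()` works from the shape table, so the full-scale networks
can be verified without materialising a gigabyte of weights. Desk-scale
variants use `widthScale < 1`: every channel count is `ceiling(scale * c)`
(rounded up to a multiple of the layer's group count), spatial arithmetic
unchanged.

One wrinkle in the reference FCN arithmetic deserves a note. With fc6
unpadded, the 500×500 input yields a 10×10 fc6 map, a 22×22 fused score
map, and a 16×-upsampled raster of 368×368 -- *smaller* than the input the
final "crop" row claims to produce. We resolve this by making the final
layer a *fit* layer: centre crop when the raster is larger than the target,
centre zero-pad when smaller. Padding (rather than rescaling) is the
geometrically correct inverse of a crop: each score cell stays aligned with
its receptive field up to a constant ~16 px offset. An earlier
implementation that bilinearly stretched the raster instead introduced a
position-dependent misalignment of up to ~70 px, under which FCN training
reliably collapsed to a constant class-prior map -- a useful cautionary
tale about upsampling-layer geometry.

A corollary of the pad geometry is that the score grid has no field of view
in a border of about 72 px (66 px at full scale): the pad's *active area*
is its central region. The synthetic scenes therefore place insects with a
matching placement margin, which we read as the physical statement that the
lure sits at the pad centre. Mosquitoes landing at the extreme pad edge are
invisible to the score map; this is a genuine limitation of the
architecture, shared by the full-scale design.

## Synthetic scenes

No recordings of a live pad are available, so every stage is exercised on
seeded synthetic scenes (`generateScene()`, `generateCountDataset()`,
`generatePatchDataset()`):

* near-white pad (`backgroundLevel` 235/255) with a mild linear
  illumination ramp (fractional amplitude 0.06) and Gaussian sensor noise
  (sigma 6 gray values);
* mosquito sprites: a dark elongated ellipse body, 4--6 one-pixel-wide
  two-segment leg strokes (drawn 4-connected so each sprite is one
  connected component), and faint low-opacity wings. Mask, bounding box and
  count are exact by construction, and all mask pixels are at least
  `minContrast` (70) gray values darker than the local noise-free
  background, so a dark-object threshold can always separate them;
* distractors: round specks, irregular blotches and elongated smudges in
  the same darkness range but without leg/wing structure. They pass the
  dark-object threshold but never enter the ground truth. The default load
  is low (about 2 per scene, varying by ±2): an observation pad attracts
  few objects other than mosquitoes, and distractors model occasional dirt
  and smudges rather than a dense field of confusers.

Desk-scale scenes are 320×320 with sprites of 20--28 px. Both numbers are
scale-consistent with the full-scale design: the score grid resolves 32 px
cells either way, and a mosquito spans one to two cells. The sprite size
spread is deliberately narrow -- at fixed camera distance the apparent size
of adult mosquitoes varies modestly, and the dark-object area filter relies
on exactly this regularity. The top label bin (5) mixes true counts 5--8
(a third of its scenes exceed 5), mirroring the pooling of ">5"
observations into label 5.

What the generator does *not* emulate: perspective and lens distortion,
motion blur of insects that move during exposure, shadows, specular
reflections, other insect species, and the continuous-video aspect of a
real station. Passing tests on synthetic scenes therefore demonstrate that
the pipeline's machinery is correct and self-consistent, not that the
trained networks would transfer to any particular camera.

## Detection defaults

Grayscale conversion uses ITU-R BT.601 luma weights; thresholding follows
the black-object convention (foreground = darker than threshold). The
automatic threshold is Otsu's method with a sanity guard: a threshold that
would mark more than 15% of a pad image as foreground is rejected and the
image treated as empty, because an Otsu split of a plain noisy background
otherwise labels half the pad as "dark". The contour area window is derived
from the sprite size range (0.25× the nominal body area of the smallest
sprite to 4× that of the largest; the nominal body area of a sprite with
longest axis L is about 0.1 L²). Components touching the border are kept;
candidates are sorted by centroid for determinism; patch crops are centred
on the box centroid and padded with the median background colour rather
than zeros, so border detections do not acquire artificial dark edges.

## Training choices

* **Optimiser.** Momentum SGD (momentum 0.9, weight decay 5e-4, both the
  usual values) with a step-down learning-rate schedule. The patch
  classifier trains exactly per the reference protocol: learning rate
  0.001, 20 epochs, 25% of patches held out.
* **Initialisation.** Fan-in-scaled Gaussians; scoring layers start at
  zero and deconvolutions as bilinear interpolation kernels (standard FCN
  practice). At the very narrow desk-scale widths a plain Gaussian
  initialisation is fragile: with 2--4 channels per layer the random
  per-layer gain varies enough that deep activations can collapse to zero
  before training starts. `initializeWeights()` therefore performs a
  layer-sequential unit-variance calibration against a small sample batch
  (output heads excluded -- a scalar head's sample standard deviation is
  near zero and rescaling it would blow up its gain).
* **Inputs** are centred to [-1, 1] inside the engine (images arrive on
  the [0, 1] scale).
* **FCN.** Desk scale trains a `widthScale = 1/32`, 2-class-head FCN for
  16 epochs at learning rate 0.05, batch size 2, with inverse-frequency
  class weights (capped at 50) computed from the label masks -- mosquito
  pixels are below 1% of a mask, and an unweighted loss is dominated by
  the background. The 2-class head is the `numClasses` parameter of the
  same architecture whose reference head has 21 channels with only two in
  semantic use (background 0, mosquito 1). The FCN's learning rate is far
  above the classifier's because the per-pixel loss is normalised over
  ~10^5 pixels.
* **Count regressor.** Trained on the score maps of all count-labelled
  training scenes (60 per label, labels clamped to 0--5), with a 15%
  validation split used purely for epoch selection (the returned weights
  are those of the epoch with the lowest validation loss), flip
  augmentation (counting is invariant under axis and point flips, so each
  training map contributes four orientations), learning rate 0.003, batch
  size 32, 25 epochs. The regressor reads the map at 115x115 -- the
  smallest AlexNet input whose pool5 grid is 3x3; at 75x75 the grid is
  2x2 and max pooling erases too much count multiplicity.
* **Score-map input mode.** `scoremapToInput()` renders the map either as
  the softmax probability image of the mosquito channel (the default
  rendering, matching how score maps are usually visualised) or as the raw
  channel stack mapped affinely into [0, 1]. The trained pipeline uses the
  channel stack: per-pixel softmax saturates -- a decisively detected
  mosquito and a marginal smudge both map to probability ≈ 1 -- whereas
  the raw score margin separates them. On identical score maps, a linear
  readout of positive score mass predicts counts with RMSE ≈ 0.5--0.6,
  while the same readout of softmax mass only reaches ≈ 0.8--1.0.

## Numerical and degenerate-input choices

Rounding of raw counts is half-away-from-zero, then clamping to [0, 5];
the mapping is total, monotone and idempotent, and `exceededTopBin` records
raw outputs above 5 (scored correct on top-bin images). Pooling uses
ceil-mode windows clipped to start inside the input (the convention that
produces the 500→250→125→63→32→16 chain). Empty detection sets, empty
scenes, zero-area boxes, labels outside [0, 5], and mismatched loss/label
pairs are all explicit errors or well-defined no-ops, as exercised in the
test suite. All randomness flows through R's RNG under caller-provided
seeds; training is bit-reproducible on single-threaded execution.

## The trigger rule

`releaseDecision()` fires when the trailing `window` (default 4)
observations are all at least `minCount` (default 1) and non-decreasing
within `slack` (default 0): a constant or increasing number of mosquitoes
is the signature of an active breeding site. The defaults are the smallest
rule consistent with "constant or increasing"; the rule is monotone in the
counts, and the test suite checks it against exhaustive enumeration of all
length-4 sequences over 0..5.

## What the desk-scale study shows -- and what it cannot

The package's acceptance study (scripts/acceptance.R) reproduces, at desk
scale, the architecture checks exactly and the patch-classifier study
comfortably (the synthetic patch task is learnable to well above 95% with
the reference protocol). The counting head-to-head is a different matter.
On synthetic pads the per-contour baseline is *strong*: detection is nearly
exact (the contrast guarantee sees to that), the patch classifier rejects
synthetic distractors reliably, and per-image counts are mostly perfect.
The reported weakness of per-contour counting -- 52% accuracy, RMSE 1.37,
with visible overcounting from misclassified contours -- arose from
real-world contour ambiguity that clean synthetic scenes do not reproduce.
Conversely the regression pipeline inherits every upstream imperfection
(bootstrapped label noise, coarse 10×10 score cells, blob-mass variation
with insect size and pose) and, at desk scale, does not reach the reported
84% / 0.42 of its full-scale, real-data counterpart. The package reports
both methods' numbers as measured; the instructive outcome of the synthetic
proxy is that the ordering of the two methods depends on conditions the
synthetic pad cannot emulate, not that one method dominates universally.

Problem sizes used by the acceptance study (the package's own choices):
8000 patches for the classifier study; 60 scenes per label (360 total) for
pipeline training with 100 auto-labelled images for the FCN; 80 held-out
test scenes per seed; everything averaged over 3 seeds.
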