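---
title: "Counting monocot leaves by deep regression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting monocot leaves by deep regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(leafcount)
```

## The problem

Monocot crops such as sorghum and maize carry elongated, stalkless leaves
that grow alternately along a central stem, bend under their own weight and
readily cross one another. Counting them from a single side-view image is a
different problem from counting rosette leaves from above: individual-leaf
segmentation breaks down exactly where the trait matters most (dense, partly
occluded canopies at later growth stages). `leafcount` therefore treats leaf
counting as *regression*: a convolutional network maps the whole plant image
to one real number, and the only label a training image needs is its integer
leaf count. Two complementary input representations are supported — the
preprocessed color crop, and a binary skeleton-structure image that strips
color and width variation while keeping the topology that determines the
count.

## Plant extraction

Greenhouse imagery has a fixed scene (rails, posts, pot) whose pixels
dominate the frame. A single background subtraction is unreliable because
illumination varies image to image, so the pipeline averages a set of
plant-free images of the same scene (50 by convention; per-pixel,
per-channel mean, rounded half-up) and works with the **absolute**
per-channel difference between a plant image and that average. Absolute
rather than signed differencing makes the pipeline indifferent to whether
the plant is darker or lighter than the scene. The difference image is
converted to grayscale with ITU-R 601 luma weights (0.299, 0.587, 0.114)
and binarized with Otsu's threshold — the value `T` in 0..254 maximizing
the between-class variance of the classes `{<= T}` and `{> T}` of the
256-bin histogram, ties resolved toward the smaller threshold. Connected
components are labeled under 8-adjacency (4-adjacency is available;
8-adjacency is the default because thin diagonal leaf strokes would
otherwise fragment), and the bounding box of the largest component is taken
as the plant. The crop is resized so its longer side is 299 px (bilinear
for image content, an exact floor-of-center nearest-neighbor mapping for
masks) and padded to 299 x 299 with white, preserving aspect ratio.

Degenerate inputs are rejected rather than silently processed: a constant
gray image has no Otsu threshold; an image whose largest difference
component is smaller than `min_plant_area` (200 px) or whose mean
difference over that component is below `min_contrast` (40 gray levels)
contains no plant.

## Skeleton structure

Uneven illumination can make parts of a leaf fade, splitting one leaf into
segments and misleading a counter. The skeleton pipeline makes the topology
explicit: Otsu binarization of the crop, Zhang–Suen thinning to a
one-pixel-wide skeleton, a dilation that re-connects small breaks, removal
of connected components smaller than 50 px (noise, by the conventional
threshold; components of exactly 50 px survive, since "smaller than" is
strict), and a second dilation that thickens the final structure. Both
dilations use a 3 x 3 square structuring element for one iteration —
kernel, size and iteration count are configurable, and the defaults were
chosen so a 1-px skeleton becomes roughly 3 px wide. Thinning is
anti-extensive and idempotent; dilation is extensive and exactly a
Minkowski sum — the test suite asserts all four properties against
brute-force oracles rather than asserting bit-exact skeletons, because
different thinning schemes legitimately differ by a pixel at stroke ends.

One subtlety: the aspect-preserving crop pads with white, and on a
three-mode histogram (dark plant, mid-gray scene, white padding) Otsu's
two-class split latches onto the padding. `binarize_plant()` therefore
excludes level-255 pixels from threshold *estimation* by default (the
threshold is still applied to the whole image, and the method falls back to
the full histogram when exclusion would leave a constant image, e.g. black
strokes on true white). Skeleton images are rendered black-on-white for
model input, which is why their occlusion analysis uses a black window.

## Augmentation

Twelve operations: the identity, vertical and horizontal axis compressions,
the vertical flip and its two compression composites (the "realistic" six —
a compressed or vertically mirrored plant still looks like a plant), then
the horizontal flip, 180-degree rotation and the four 90-degree
rotation/flip composites (the "non-realistic" six). Compression scales one
axis by a configurable factor (default 0.5 — no canonical value exists, and
0.5 both matches the visual intent and guarantees the padding path is
exercised) about the image center and pads with pure white back to
299 x 299. Flips and rotations are exact pixel permutations, so the group
identities (double flip, quadruple rotation, rot180 = flip_h after flip_v)
hold bit-exactly and are tested that way. Expansion applies only to the
training split: 800 training rows become 4800 under the realistic set and
9600 under the full set, while validation and test rows pass through
byte-identical — labels are never touched, since none of these transforms
changes how many leaves a plant has.

## The regression network

The model is a strided convolutional stack (3 x 3 valid convolutions,
stride 2, ReLU; base widths 32-64-128-192) closed by global average pooling
and a single-unit dense layer that emits the raw, unrounded count. The GAP
head is the load-bearing design element: it makes the output a spatial
average of local evidence, which is what lets both Grad-CAM (the output
gradient with respect to the final feature map is exactly `w_c / (H*W)`)
and the occlusion analysis read the model's spatial attention.

Two backbones share this head contract. `reduced` (the default, and the
one all tests use) applies a 2x average pooling at the input and scales the
widths by 0.25, giving ~20k parameters and an 8 x 8 final feature map —
small enough to train on one CPU in minutes. `full` is the same stack at
full width without input pooling (~315k parameters). Both are the
package's own architecture: no pretrained deep backbone is bundled, and
`pretrained_init` semantics from transfer-learning workflows do not apply —
training always starts from seeded He-normal initialization.

Training minimizes mean squared error with minibatch RMSprop (decay 0.9,
epsilon 1e-8), batch size 16, all parameters trainable, no early stopping;
inputs are scaled from [0, 255] to [-1, 1]. The conventional learning rate
for long fine-tuning runs is 1e-4 over 500 epochs. For desk-scale runs that
start from random weights and last a few dozen epochs, that rate cannot
move a freshly initialized scalar head to the label scale (RMSprop's
normalized steps are of order the learning rate), so the package's
reference experiment uses 0.01 with a 0.97 per-epoch decay; the decay damps
RMSprop's characteristic oscillation once the loss plateaus. Gradients are
exact backpropagation (verified against numerical differentiation in the
tests), and a fixed seed reproduces the loss curve bit for bit. The
recorded per-epoch training loss is accumulated from pre-update predictions
within the epoch, so for a single full-set batch the first entry equals the
initial model's MSE exactly — a property the tests exploit as an oracle.

## Synthetic plants: what they emulate and what they do not

Because no public monocot greenhouse dataset ships with the package, the
generator renders the study conditions: a fixed equipment scene (vertical
illumination gradient, two rails, a post, a dark pot) shared by every image,
per-image illumination jitter (uniform, +/-8 gray levels by default) and
low-amplitude sensor noise; a vertical stem; `leaf_count` tapering
quadratic-Bezier leaf strokes attached alternately along the stem, with
per-leaf lengths drawn from 0.30-0.42 of the canvas height (leaves on one
plant are similar in length, which keeps plant area an imperfect but not
degenerate cue for count); optional forced leaf-leaf crossings for
occlusion studies; and small dark distractor blobs standing in for soil and
grass. Plants are darker than the scene, the usual contrast polarity of
RGB greenhouse imagery. The default canvas is 512 x 512 (the generator is
resolution-agnostic); ground truth includes per-leaf masks and tip
coordinates, which exist only to power oracles — real datasets have only
count labels, and nothing in the training path reads them.

What the synthetic data does *not* emulate: leaf texture and venation,
species-specific morphology, tassels, specular lighting, camera distortion.
Passing tests on this data demonstrates that the pipeline's machinery is
correct and that the regression approach works when its assumptions hold;
it does not certify performance on real sorghum or maize.

## The desk-scale reference experiment

`train_synthetic_benchmark()` fixes the package's reference conditions: 300
training and 50 test plants (no validation split), uniform counts 2-6, no
occlusion, preprocessing against a 50-image background set, the reduced
backbone, 30 epochs at learning rate 0.01 with 0.97 decay, everything
driven by one seed. These sizes were chosen as the smallest experiment in
which generalization is meaningfully measurable; the run takes a few
minutes of CPU. With seed 1 it reaches held-out RMSE 0.33, R^2 0.94 and
accuracy 0.94 — numbers the acceptance script recomputes from scratch, not
constants of the package.

## Interpretation

The occlusion map paints an opaque window (10 x 10 by default, roughly one
leaf width; stride 5; colored like the background — white for color crops,
black for skeleton images) at every grid position and records the *signed*
difference between the occluded prediction and the ground truth, positive
meaning over-count; a 299-px image yields a 58 x 58 grid. Cells are not
interpolated or averaged per pixel: each cell is one window position, and
rendering upsamples nearest-neighbor.

Grad-CAM weights each final-feature-map channel by the spatial mean of the
output's gradient with respect to it, sums, rectifies, and min-max
normalizes to [0, 1] (an all-equal map normalizes to all zeros rather than
dividing by zero). With the GAP + single-unit head this gradient has the
closed form `w_c / (H*W)`, which the implementation uses directly; the
tests verify the formula against the head contract. The optional sigmoid
emphasis `1 / (1 + exp(-k (v - 0.5)))` with steepness `k = 10` (center and
steepness are conventions of this package; they have no canonical values)
sharpens the boundary between contributing and non-contributing regions.

`leaf_feature_diagnostics()` quantifies two qualitative expectations on a
synthetic reference plant. First, Grad-CAM mass should sit on leaves
rather than stem: it compares mean map values over 21 x 21 neighborhoods
of the known leaf tips against the mean over the *bare* stem — the lowest
fifth of the stem, below every leaf attachment. The restriction matters:
with an 8 x 8 feature map each cell spans ~37 px, so upper-stem pixels
share cells with crossing leaves and would contaminate the contrast. On
the reference fixture (and across other seeds checked the same way) the
tip mean exceeds the bare-stem mean. Second, it reports the prediction
change when a window severs a leaf near its base versus near its tip. On
large fine-tuned models, base-severing is expected to raise the count (the
distal segment reads as an extra leaf) and tip-severing to lower it. The
desk-scale surrogate does not reproduce this direction: a ~20k-parameter
network trained for 30 epochs responds to foreground area, not to
connected-component structure, so both deltas are small and base-severing
typically lowers the prediction slightly. The diagnostic therefore
*reports* these deltas without asserting their sign — a documented
limitation of the scaled-down model, not of the measurement.

## Numerical conventions and degenerate cases

* Rounding: background averaging rounds half-up; accuracy rounds
  predictions half-up (`floor(x + 0.5)`), with banker's rounding available —
  no canonical rule exists for "correct prediction", so the choice is
  documented rather than claimed.
* R^2 with constant ground truth is an error, not a sentinel; the pipeline's
  report writes `null` for it on degenerate tiny test splits.
* Otsu on a constant image is an error; ties in the variance maximization
  take the smallest threshold, and the brute-force oracle in the tests uses
  the same tie rule with a 1e-12 guard against float noise.
* Component labels are deterministic: ordered by first pixel in
  column-major scan; equal-area ties for "largest" resolve to the smallest
  label.
* All RNG use is localized: rendering and training save and restore the
  caller's `.Random.seed`.

## Known limitations

The backbone is a compact stack, not a bundled large pretrained network;
results on real imagery will not match fine-tuned deep models. Thinning
artifacts ("extra tips" where a leaf's width varies sharply) are inherited
from the skeletonization approach and not corrected. The synthetic scene
is a stand-in with no claim of visual realism. Occlusion maps cost one
forward pass per grid cell (3364 for the default geometry), which is
seconds per image on the reduced backbone but scales linearly with model
cost.
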