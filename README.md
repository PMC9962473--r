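# leafcount

Leaf counting for monocot plants (sorghum, maize) from greenhouse-style RGB
images, by deep regression on preprocessed plant crops and skeleton-structure
images.

Leaf number is a standard phenotyping trait — it tracks growth stage and
correlates with biomass — but monocot leaves are elongated, flexible and
readily occlude one another, which defeats the top-view instance-counting
approaches that work for rosette plants. `leafcount` implements a
regression-based alternative: a convolutional network maps a whole plant
image directly to a real-valued leaf count, so the only annotation a
training image needs is one integer.

The package covers the full pipeline:

* **Preprocessing** — an average of ~50 plant-free background images of the
  same scene is subtracted from each plant image; the absolute difference is
  converted to grayscale (ITU-R 601 luma), binarized by Otsu's method
  (threshold `T` maximizes the between-class variance
  `omega_0 omega_1 (mu_0 - mu_1)^2` of the 256-level histogram), and the
  largest connected component's bounding box is cropped and resized to the
  network input of 299 x 299 with white padding.
* **Skeletonization** — the crop is binarized again, thinned to a
  one-pixel-wide topology-preserving skeleton (Zhang–Suen), dilated with a
  3 x 3 square element to reconnect weak leaf segments, components smaller
  than 50 px are removed as noise, and a second dilation strengthens the
  final skeleton-structure image.
* **Augmentation** — the original plus eleven label-preserving geometric
  transforms (axis compressions, flips, rotations), split into a *realistic*
  half of six ops and a *non-realistic* half; an 800-image training split
  becomes 4800 rows under the realistic set and 9600 under the full set,
  while validation and test splits are never touched.
* **Regression model** — a strided convolutional stack closed by global
  average pooling and a single-unit dense head emitting the raw (unrounded)
  count; trained with minibatch RMSprop (batch 16) on mean squared error.
  The default `reduced` backbone runs at desk scale on a CPU.
* **Evaluation** — RMSE `sqrt(sum (y_i - yhat_i)^2 / n)`, coefficient of
  determination `R^2 = 1 - SS_res / SS_tot`, and accuracy (fraction of
  predictions whose half-up rounding equals the label), plus per-count
  prediction distributions for violin plots.
* **Interpretation** — occlusion-sensitivity maps (a 10 x 10
  background-colored window slid with stride 5; each cell records
  `prediction - ground truth`) and Grad-CAM on the final convolutional
  feature map with optional sigmoid emphasis.
* **Synthetic plants** — a procedural generator renders monocot-style
  plants (vertical stem, alternating curved Bezier leaf strokes, pot and
  equipment background with illumination jitter) with exact ground-truth
  counts and per-leaf masks, so every stage is testable end to end without
  proprietary greenhouse data.

## Worked example

```r
library(leafcount)

# the desk-scale reference experiment: 300 training / 50 test synthetic
# plants with 2-6 leaves, reduced backbone, 30 epochs (~7 min on one CPU)
bm <- train_synthetic_benchmark(seed = 1)
print(bm$eval)
#> Leaf-count evaluation on 50 images
#>   RMSE     : 0.3272
#>   R-squared: 0.9439
#>   Accuracy : 0.9400

# predict a new plant
spec  <- plant_spec(leaf_count = 5, seed = 555)
plant <- render_plant(spec)
crop  <- preprocess_pipeline(plant$image, bm$avg_background)
predict(bm$model, crop)
#> [1] 5.600468

# where does the model look?
cam <- grad_cam(bm$model, crop)
overlay <- render_overlay(emphasize(cam), crop)
write_image_png(overlay, "cam.png")
```

The printed evaluation means: on the 50 held-out synthetic plants the raw
predictions deviate from the true counts by 0.33 leaves RMS, explain 94% of
the count variance, and round to the exact count for 94% of plants. The
Grad-CAM overlay highlights leaf arcs and tips and stays dark on the bare
stem and pot.

A YAML-configured end-to-end run (synthesis through evaluation and
explanation) is available as `run_pipeline("config.yaml")`, and
`inst/cli/leafcount.R` is a thin command-line dispatcher over the same
functions.

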