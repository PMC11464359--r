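# seedstand

Stand counting — how many established seedlings are in a plot — is a core
phenotyping measurement for row crops such as sorghum, and counting them by
hand across a breeding trial is slow. `seedstand` implements the classical
image-analysis route for nadir UAV RGB imagery, end to end and fully
testable offline:

* **Color vegetation indices.** Eight single-channel transforms on
  chromatic coordinates (r = R/(R+G+B), …): EXG (2g − r − b), Cg
  (0.4g − 0.3r − 0.1b), EXG−EXR (3g − 2.4r − b), EXR (1.4r − g), GBDI
  (g − b), NGBDI ((g−b)/(g+b)), NGRDI ((g−r)/(g+r)) and the HSV saturation
  component.
* **Otsu segmentation.** Maximum inter-class variance thresholding
  S(t) = ω₀(μ₀−μ)² + ω₁(μ₁−μ)² over 256 gray levels, with a quantitative
  foreground/background separability analysis (normalized criterion η and
  histogram overlap) over 20×20 px patch samples.
* **SVM counting.** A maximum-margin pixel classifier (plant vs soil) on
  color features, morphological cleanup, and 8-connected components as
  seedling detections with per-component boxes.
* **Evaluation.** Greedy IoU matching, precision/recall/F1, all-point
  interpolated AP and mAP@0.5, and count regression R², RMSE and relative
  RMSE (% of the mean true count).
* **Data plumbing.** YOLO-format label I/O, rectangle-annotation JSON →
  YOLO conversion, stratified 2:1 train/validation splitting, YAML configs.
* **A synthetic field generator.** Seeded, bit-reproducible scenes of
  row-planted rosettes on textured red-yellow soil with weeds, shadows,
  illumination drift and sensor noise, rendered with proper sensor
  integration so that flying higher really costs resolution. Ground truth
  (boxes, masks, per-plant areas) is exact, so every pipeline stage is
  testable without any external dataset.

## Worked example

Simulate one 15 m scene, segment it with EXG + Otsu, train the pixel SVM
on patch samples, and count:

```r
library(seedstand)

spec  <- scene_spec(altitude_m = 15, n_seedlings = 20, rng_seed = 3)
scene <- generate_scene(spec)

samp  <- build_samples(scene$image, scene$truth, n_patches = 15,
                       rng_seed = 5, refine_with_index = "EXG")
model <- train_pixel_svm(samp)
mask  <- classify_pixels(model, scene$image)
cc    <- count_components(mask, min_area_px = scaled_min_area(60, 15))
cc$count
#> [1] 19

gt <- yolo_to_pixel(scene$truth$boxes, nrow(mask), ncol(mask))
m  <- match_detections(cc$detections, gt)
detection_metrics(m)
#>        P        R       F1
#> 1.000000 0.950000 0.974359
```

19 of the 20 seedlings are found with no false positives; the one miss is
a deliberately overlapped pair whose merged canopy a connected-component
counter cannot split. The interesting behavior is across
altitudes, which the experiment driver reproduces at trial scale — 36
images per altitude, split 24 train / 12 validation per altitude:

```r
res <- run_experiment(experiment_config(seed = 1))
res$results
#>   altitude model     P     R mAP50    F1    R2  RMSE RRMSE_pct
#> 1       15   SVM 0.984 0.950 0.942 0.967 0.981 0.866      3.97
#> 2       30   SVM 0.975 0.948 0.933 0.961 0.976 0.957      4.63
#> 3       45   SVM 0.980 0.943 0.929 0.961 0.965 1.000      4.60
```

Validation-count agreement (R² against the identity line) is highest at
15 m and declines monotonically with altitude as small, late-emerged
seedlings fall below the resolution floor and neighboring canopies merge —
the qualitative pattern reported for UAV stand counting in the field. The
separability table in `res$separability` shows EXG among the top indices
by η with a clearly smaller plant/soil histogram overlap than the
blue-difference indices (GBDI, NGBDI), which is why EXG is the default
working index.

A thin command-line front-end covers the same steps
(`exec/seedstand generate|index|segment|train|count|evaluate|experiment`).

## Documentation

The methods vignette (`vignettes/seedstand-methods.Rmd`) describes the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, and the
numerical conventions (quantization, tie-breaking, degenerate inputs).
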