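Package: seedstand
Title: Crop Stand Counting from UAV RGB Imagery with Color Indices, Otsu
    Thresholding and SVM Pixel Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, fully testable pipeline for counting row-planted
    crop seedlings (e.g. sorghum) in nadir UAV RGB imagery. Provides eight
    color vegetation indices (EXG, EXR, EXG-EXR, Cg, GBDI, NGBDI, NGRDI and
    the HSV saturation component), maximum inter-class variance (Otsu)
    threshold segmentation with a quantitative fg/bg separability analysis,
    a supervised SVM pixel classifier with morphological cleanup and
    8-connected component counting, detection and count-regression metrics
    (precision, recall, F1, AP/mAP at IoU 0.5, R2, RMSE, RRMSE), YOLO-format
    label I/O, and a seeded synthetic field-image generator that emulates
    multi-altitude UAV capture so the whole pipeline runs against known
    ground truth without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    ggplot2,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
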