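Package: aacquant
Title: Automatic Abdominal Aortic Calcification Scoring from Lateral Lumbar Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies abdominal aortic calcification (AAC) on lateral lumbar
    radiographs with the 24-point Kauppila score. Provides a synthetic phantom
    generator with ground-truth scores known by construction, stage-one and
    stage-two image preprocessing, a compact trainable 2D U-Net for
    vertebra/aorta and calcification segmentation, a geometric scoring engine
    that partitions the aorta by vertebral level, classifies calcifications as
    anterior or posterior wall and converts longitudinal coverage ratios into
    per-segment scores, a total score (0-24) and a severity category, plus
    segmentation metrics (Dice, volume similarity, Hausdorff distance) and
    score-agreement statistics (Kendall's W, Pearson correlation, adjusted R2,
    Bland-Altman limits of agreement, severity confusion and accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
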