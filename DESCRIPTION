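Package: whaletiles
Title: Tile-Based Whale Detection in Aerial and Satellite Ocean Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A semi-automated pipeline for surveying large whales in very
    high-resolution ocean imagery. Aerial-resolution scenes are down-sampled
    to satellite ground-sample distance, split into 32x32-pixel tiles, and
    used to train a two-class (whale / water) convolutional network with
    imbalance-aware batch sampling; the trained model triages satellite
    tiles for expert review. Includes Gram-Schmidt pansharpening of
    multispectral imagery, the 20-percent whale-retention labelling rule,
    stratified k-fold splits, histogram-of-oriented-gradients baselines
    (ridge and C-SVC), water-positive precision/recall/F1 reporting, and a
    seeded synthetic ocean-scene generator so the whole pipeline is testable
    without proprietary imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jsonlite,
    MASS,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
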