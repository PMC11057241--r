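Package: ccphase
Title: Cell-Cycle Phase Prediction from DNA-Stain High-Content Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting the cell-cycle phase (G1, early S,
    S/G2/M) of individual nuclei from texture and morphology features of a
    low-toxicity DNA-stain channel, using thresholded Fucci reporter
    intensities as ground-truth labels. Includes a synthetic multi-channel
    plate-imaging simulator with per-nucleus ground truth, sliding-parabola
    background correction and watershed nucleus segmentation, a frozen
    240-feature catalog (intensity, basic morphology, SER texture filters,
    Haralick co-occurrence statistics, and STAR intensity-weighted
    morphology on raw and filtered image variants), Fucci threshold gating
    with apoptotic-nucleus exclusion, train/validation sampling with
    min-max normalization, four classifier families compared by 10-fold
    cross-validation with random-forest feature importance, and
    per-condition reporting with Wilcoxon rank-sum comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    e1071,
    ggplot2,
    jsonlite,
    ranger,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
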