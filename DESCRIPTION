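Package: tabletTMT
Title: Tablet-Based Trail Making Test Kinematics and Split-Half fMRI
    Activation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing digitized Trail Making Test (TMT)
    performance recorded with an MRI-compatible tablet, together with the
    split-half NPAIRS (prediction/reproducibility) framework for
    optimizing fMRI preprocessing pipelines and extracting LDA-PCA
    activation maps. Includes a synthetic-data generator for stimulus
    layouts, block paradigms, stylus kinematics logs and simulated BOLD
    runs with known ground truth; stylus metrics (seconds per link, dwell
    time, link length, contact force) with mixed-design group statistics;
    a library of denoising steps applied in a fixed order with task-signal
    protection; per-subject pipeline and model-complexity selection by the
    Euclidean distance D(P, R) from ideal prediction and reproducibility;
    reproducible Z-scored maps (rSPMZ); and group-level PCA with split-half
    resampling, FDR thresholding, conjunction masks, cluster tables and
    Jaccard overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
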