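Package: fatquant
Title: Quantifying Supraspinatus Muscle Atrophy and Fatty Infiltration from Scapular Y-View MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-assisted quantification of supraspinatus muscle atrophy
    and fatty infiltration on scapular Y-view magnetic resonance slices.
    Implements region-restricted adaptive Otsu thresholding with a conditional
    histogram-equalization gate, occupation-ratio computation, segmentation
    agreement metrics (Dice, accuracy, sensitivity, specificity, relative area
    difference), leakage-safe flip and brightness histogram-matching
    augmentation with a k-fold cross-validation harness, a small fully
    convolutional segmentation network, cohort-level statistics (one-way ANOVA
    with Bonferroni post hoc tests, Pearson correlation, weighted kappa,
    intraclass correlation), and a synthetic phantom generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
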