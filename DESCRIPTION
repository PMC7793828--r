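Package: lesionbench
Title: Simulated-Lesion Benchmarking of Automated Brain Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lesion-induced error in automated brain-volume
    measurement by transplanting focal lesions into lesion-free T1-weighted
    volumes in a fully crossed design. Builds chimeric images whose lesion
    intensities are transferred through a unit-invariant (z-scored) intensity
    space, measures hemispheric cortex and cerebral-white-matter volumes with
    a pluggable segmenter (a built-in intensity-classifying mock or an
    external-tool adapter), recodes hemispheres to lesioned vs contralesional,
    computes percent volume difference (PVD), and fits crossed-random-effects
    linear mixed models contrasting global versus focal error. Includes a
    synthetic phantom and lesion generator so the full pipeline runs without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
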