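Package: hippot2
Title: Automated Hippocampal T2 Relaxometry and Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantitative T2 relaxometry of the
    hippocampus from dual-echo spin-echo MRI, aimed at the radiological
    work-up of hippocampal sclerosis in temporal lobe epilepsy. Computes
    voxelwise T2 maps from a closed-form monoexponential fit, applies a
    rigid world-space transform to bring hippocampal segmentations onto the
    T2 map, removes partial-volume cerebrospinal fluid by morphological
    erosion and a T2 cutoff, corrects hippocampal volumes for intracranial
    volume by control-derived regression, derives normative reference
    ranges, and classifies hippocampi as pathologic or non-pathologic from
    (volume, T2) features by logistic regression. Ships a digital dual-echo
    phantom and cohort generator so the whole pipeline is testable without
    scanner data, plus Bland-Altman agreement tools for scan-rescan
    reproducibility studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
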