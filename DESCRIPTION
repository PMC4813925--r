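Package: lumentrace
Title: Automatic Carotid Lumen Centerline Detection in B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the common carotid artery (CCA) lumen centerline on
    longitudinal B-mode ultrasound images. A contrast-invariant phase-symmetry
    map of dark tubular structures is computed from a band-pass monogenic
    signal decomposition, lumen centerline candidates are extracted by
    dynamic-programming path optimization of the symmetry map, and the true
    lumen is selected among the candidates with a one-dimensional logistic
    gate on symmetry, intensity or lumen-to-wall contrast features followed by
    a bottom-most positional heuristic. Includes domain-knowledge parameter
    derivation from population diameter statistics, Gaussian and speckle noise
    models for robustness studies, a synthetic carotid phantom generator with
    ground-truth wall annotations, and a cross-validated evaluation harness
    with ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
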