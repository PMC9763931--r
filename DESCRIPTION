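Package: vhindex
Title: Composite Vascular Health Index from Microvascular Phenotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an age-normalized composite Vascular Health Index (VHI)
    for rodent microvascular studies from three classes of measurement:
    agonist concentration-response dilation fitted with a four-point logistic
    model, passive circumferential stress-strain wall mechanics fitted with an
    exponential stiffness model, and tissue microvessel density. Component
    values are scored as percent of an age-, vascular-bed-, and study-matched
    lean control standard and averaged (3- or 5-component variants) into a
    single index. Includes criterion-validity (biomarker correlation) and
    discriminant-validity (group separation) analyses, tidy CSV readers and
    writers for per-animal measurement tables, and a synthetic cohort
    generator with known ground truth for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
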