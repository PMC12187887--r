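Package: txtrace
Title: Claims-Based Phenotyping of Immunosuppression After Kidney Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying maintenance immunosuppression in kidney
    transplant recipients from administrative claims. Provides a synthetic
    national-claims generator with per-patient ground truth, rule-based
    phenotyping algorithms (index transplantation and eligibility, drug-class
    exposure timelines, combination and switch detection, an infusion-pattern
    algorithm identifying belatacept use, and a proxy rule dating graft loss),
    Kaplan-Meier and Aalen-Johansen survival estimation with death as a
    competing risk, and reporting of treatment-pattern tables by transplant
    era. All inputs and outputs are plain data frames so the pipeline composes
    with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    survival,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
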