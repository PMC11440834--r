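Package: nafkinetics
Title: Kinetic Analysis of Dynamic [18F]NaF PET Bone Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of bone metabolism from dynamic [18F]sodium
    fluoride PET. Implements the irreversible two-tissue (Hawkins)
    compartment model with nonlinear-regression fitting of six parameters
    (K1, k2, k3, blood fraction, partial-volume fraction, input
    dispersion), graphical Patlak analysis, rule-based image-derived
    input-function extraction from 4D dynamic volumes, a synthetic-cohort
    generator emulating regional knee time-activity data across uptake
    strata, and a retrospective scan-duration truncation study with
    stratified normalized-error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    RNifti,
    EBImage,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
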