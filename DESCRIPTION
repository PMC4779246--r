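Package: amtox
Title: Alveolar Macrophage Assay Pipeline for Nanomaterial Hazard Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the NR8383 rat alveolar macrophage in vitro assay
    prediction model for distinguishing biologically active from passive
    (nano)materials. Covers normalization of raw plate-reader endpoints (LDH,
    beta-glucuronidase, TNF-alpha, H2O2), determination of in vitro
    lowest-observed-adverse-effect concentrations by two-way ANOVA with
    Dunnett's many-to-one comparison, conversion of mass-based doses to BET
    surface-area doses, threshold-based active/passive classification with the
    two-of-four endpoint rule, and Cooper concordance statistics against rat
    short-term inhalation study categorizations. Ships the published
    20-material evaluation as packaged fixtures and a synthetic replicate
    generator for operating-characteristic studies.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mvtnorm,
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
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
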