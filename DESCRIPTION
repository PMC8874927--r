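Package: matcvrisk
Title: Maternal Cardiovascular Risk Detection from Visit-Centric EHR Extracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline that turns fragmented, visit-centric
    electronic health record extracts into anonymized, normalized patient
    timelines and runs a deterministic, rule-based cardiovascular risk
    stratification engine over each prenatal encounter. Includes a synthetic
    cohort generator with planted risk trajectories and known ground truth,
    cohort extraction with configurable inclusion and exclusion criteria,
    de-identification (geographic generalization, index-visit day offsets,
    keyed pseudonymization with a local master key, free-text stripping),
    record harmonization with a three-level category scheme and unit
    normalization, per-encounter standard and red-flag risk profiling against
    an established maternal cardiovascular risk-factor catalog, and
    quantification of the lead time between algorithmic detection and the
    recorded clinical diagnosis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    withr,
    yaml,
    digest,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
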