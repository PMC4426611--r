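Package: ventflux
Title: Sulfur Flux and Carbon Fixation Analysis for Flow-Through
    Respirometry of Chemosynthetic Symbioses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes high-pressure flow-through respirometry experiments on
    chemoautotrophic animal-microbe symbioses. Converts cyclic voltammetric
    scan series into per-interval analyte concentrations with transitory-scan
    removal and detection-limit censoring, derives signed mass-specific net
    sulfur uptake and excretion rates by control-differenced mass balance,
    computes carbon-fixation rates from 13C-bicarbonate tracer incorporation
    in gill tissue, predicts gill mass from body-mass allometry, attributes
    aquarium-level sulfur oxidation to individuals via carbon-to-sulfur
    stoichiometry, and provides exact small-sample nonparametric tests by
    full enumeration. A synthetic-data generator emits complete in-silico
    experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
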