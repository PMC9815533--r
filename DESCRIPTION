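Package: syncom
Title: Constraint-Based Modeling of Acetogen-Solventogen Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the model-driven design of two-species anaerobic
    co-cultures with genome-scale metabolic models: reading and writing
    models in SBML Level 3 (with flux-bound and objective annotations) and
    a tabular dialect, flux balance analysis and flux variability analysis
    on a simplex backend, uniform flux sampling of the steady-state
    polytope, declarative model-curation recipes, single and pairwise
    carbon-source growth screening, construction of three-compartment
    community models with a shared extracellular namespace, feasibility
    scans over species ratio and growth rate in environmental-flux units,
    and carbon bookkeeping for fed-batch fermentations (lactate conversion,
    theoretical acetate from CO2, product stoichiometry). Ships toy
    acetogen and solventogen networks and a synthetic fed-batch generator
    as a desk-scale test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
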