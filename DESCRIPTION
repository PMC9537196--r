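Package: sbtabflow
Title: SBtab-Centred Modeling Workflow for Subcellular Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular workflow for building, analysing and estimating
    biochemical reaction-network models stored in the SBtab spreadsheet
    format. Reads and writes SBtab model+data documents (TSV file sets,
    read-only xlsx), compiles reaction networks into ODE right-hand sides,
    detects conserved moieties and Wegscheider thermodynamic constraints
    from the stoichiometric matrix, simulates experiment protocols
    (equilibration followed by stimulus inputs such as calcium spike
    trains and dopamine transients), estimates parameters in log10 space
    against time-series data with a standard-deviation-weighted
    least-squares objective, performs variance-based global sensitivity
    analysis (Sobol first-order and total-order indices on a Saltelli
    design), and exports models to SBML Level 2 Version 4, NEURON NMODL
    (MOD) and VFGEN vector-field formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    xml2,
    readxl,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
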