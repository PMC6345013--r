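Package: stilflux
Title: Constraint-Based Flux Analysis of a Resveratrol-Producing Fungal
    Metabolic Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing, curating and interrogating
    genome-scale metabolic models of secondary-metabolite producing fungi,
    motivated by stilbene (resveratrol) biosynthesis in grape endophytes.
    Provides gene-protein-reaction (GPR) boolean logic, stoichiometric
    matrix assembly, elemental and charge balance checking, duplicate
    reaction detection, SBML/JSON/TSV model input and output,
    ortholog-threshold draft reconstruction and greedy gap filling, biomass
    pseudo-reaction assembly from macromolecular composition and genome GC
    content, flux balance analysis (FBA) on a built-in bounded-variable
    simplex, flux variability analysis, robustness scans, metabolite
    connectivity ranking, single-gene deletion essentiality screens,
    minimization of metabolic adjustment (MOMA) via quadratic programming,
    an overexpression-target scan for product-enhancing reactions, and
    growth-phenotype validation scoring. A deterministic synthetic
    mini-network spanning glycolysis, the pentose phosphate, shikimate,
    phenylpropanoid and malonyl-CoA pathways allows every pipeline stage to
    run without external data.
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
    Matrix,
    quadprog,
    readr,
    rlang,
    tibble,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
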