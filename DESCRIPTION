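Package: orbgap
Title: Frontier Bond-Orbital Gap Prediction for Cycloaddition Reactivity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting cycloaddition reactivity of enophiles from
    molecular structure.  A lightweight molecular-graph layer parses SMILES and
    SDF input, perceives aromaticity and extracts conjugated pi systems.  A
    parameterized Hueckel molecular-orbital engine computes pi orbital spectra
    and fragment-localized frontier bond orbitals (HOBO/LUBO) that serve as
    surrogate energy labels.  Hashed circular and path fingerprints featurize
    molecules for elastic-net, support-vector and neural-network regression
    models; a grid-search stage cross-validates descriptor/model combinations
    into an accuracy heat map.  A screening stage predicts orbital energies for
    candidate enophiles, composes HOBO/LUBO gaps against a cycloheptatriene
    reference substrate, ranks candidates and classifies reactive clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    jsonlite,
    stats,
    graphics,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
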