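Package: idpal
Title: Active-Learning Design of Intrinsically Disordered Protein Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-objective active-learning framework for designing short
    intrinsically disordered protein (IDP) sequences that trade off condensate
    thermodynamic stability, measured by the second virial coefficient B2,
    against condensed-phase internal dynamics, measured by the chain
    self-diffusion coefficient D. Implements the coarse-grained HPS pair
    energy model (Ashbaugh-Hatch van der Waals plus Debye-Hueckel
    electrostatics), a 30-dimensional sequence featurization (amino acid
    composition plus ten chain-level descriptors including SCD and SHD),
    Gaussian-process surrogates and a random-forest phase-separation
    classifier, expected-hypervolume-improvement (EHVI) acquisition with a
    sequence-similarity penalty, genetic-algorithm sequence proposal, Pareto
    front bookkeeping with convergence metrics, and post-hoc counterfactual
    analysis. Physical property evaluation is pluggable: desk-scale engines
    (B2 from a potential of mean force, equation-of-state phase analysis,
    diffusion from mean-squared displacement) and a synthetic oracle with a
    planted Pareto front are included so the full design loop runs without
    molecular dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    randomForest,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
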