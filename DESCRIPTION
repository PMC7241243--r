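Package: diffconn
Title: Differential Connectivity Analysis for Feature Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential connectivity analysis for feature-feature association
    networks built from correlation or mutual information, as used in
    metabolomics and other omics fields. Node connectivity is the sum of
    absolute association weights and its between-group difference is tested
    with a column-permutation null. Includes four discrete entropy estimators
    (empirical, Miller-Madow, James-Stein shrinkage, Schurmann-Grassberger)
    for mutual information, generators for structured random correlation
    matrices (Toeplitz, hub, vine/average), a kinetic ODE population sampler
    with per-individual parameter jitter and a global perturbation multiplier,
    closed-form correlation/mutual-information relationships, and scripted
    type-I-error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
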