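Package: jplogp
Title: Atomic-Contribution Prediction of Octanol-Water Partition
    Coefficients with Atom-Type Holograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the octanol-water partition coefficient (logP) of
    organic molecules by an atomic contribution method. A hierarchical
    atom typer assigns every atom, hydrogens included, a six-digit code
    combining formal charge, element, heavy-atom degree and an
    element-specific local-environment class. Molecules are represented
    as count holograms over these codes; per-type coefficients are fit
    by QR least squares against consensus logP targets, and predictions
    are either the coefficient-weighted hologram sum or a
    library-corrected estimate that adjusts a similar reference
    compound's experimental logP by a signed difference hologram.
    Includes count-Tanimoto similarity search, a rarest-first targeted
    sampler for building training subsets with guaranteed atom-type
    coverage, evaluation utilities and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
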