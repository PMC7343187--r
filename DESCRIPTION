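Package: rimabk
Title: Kinetic, Stochastic and Translatome Models of Ribosomal Protein
    Glutamation by the RimABK System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the post-translational glutamation of ribosomal protein
    RpsF by the bacterial RimABK pathway. Builds mass-action binding networks
    for the glutamate ligase RimK and its regulators (the trigger
    phosphodiesterase RimA, the poly-glutamate protease RimB and the second
    messenger cyclic-di-GMP), enforces thermodynamic cycle consistency, and
    solves for steady-state species occupancies. Composes multi-state
    Michaelis-Menten ATPase rates from those occupancies and fits kinetic
    parameters to rate data by seeded global optimization. Simulates
    poly-glutamate chain dynamics on RpsF under competing extension and
    end-cleavage, at single-chain and cell-population scale. Quantifies
    ribosome-profiling data by strand-specific centre-weighted coverage and
    RPKM, classifies translatome regulons from paired contrasts, and filters
    differential protein-abundance tables. A synthetic-data generator emulates
    every input so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    pracma,
    minpack.lm,
    tibble,
    dplyr,
    withr,
    yaml,
    jsonlite,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
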