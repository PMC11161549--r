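Package: gcbranch
Title: Multitype Branching-Process Models of Germinal Center B-Cell
    Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic modeling of germinal center (GC) B-cell dynamics as a
    multitype age-dependent branching process with time-inhomogeneous Poisson
    immigration. Provides exact inversion sampling of founder-cell seeding and
    closed-form first-arrival laws, event-driven simulation of clonal
    expansion, Malthusian/Perron-Frobenius asymptotics, deterministic
    first- and second-moment renewal solvers, temporal alpha and beta
    diversity indices with their branching-process limits, an infinite-type
    model of clonal dominance turnover, and a five-compartment somatic
    hypermutation kernel describing drift of B-cell receptors relative to a
    germline gene and a target broadly neutralizing antibody.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
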