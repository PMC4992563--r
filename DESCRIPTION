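Package: evofba
Title: Evolutionary Dynamic Flux Balance Analysis of Serial-Transfer Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples dynamic flux balance analysis (dFBA) of stoichiometric
    metabolic models to an evolutionary algorithm over substrate-uptake
    capacities under a fixed total-uptake budget. Simulates serial-transfer
    batch cultures (daily 1:100 dilution in glucose minimal medium) in which
    mutations redistribute a constant total uptake capacity across substrates,
    allowing cross-feeding specialists to emerge from an acetate-overflowing
    ancestor. Includes a two-stage (growth-maximizing, then flux-minimizing)
    FBA solver, a packaged Escherichia coli core model, a fast analytically
    tractable toy overflow model, lineage analysis, diauxic-shift detection
    and flux snapshot protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
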