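Package: eggboxr
Title: Egg-Box Analysis of Ion-Induced Alginate Gelation from Elemental
    Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting energy-dispersive X-ray (EDX) elemental
    compositions of divalent-metal alginate hydrogels within the egg-box
    model of ionotropic gelation. Rescales atomic-percent tables to the
    alginate C12 block, classifies junction-zone types from the cation
    occupancy X, decomposes the measured metal content into structural
    cross-linking cations, physically adsorbed salt associates, in-cell
    hydrated complexes and hydration water, and computes exact combinatorial
    probabilities of the seven egg-box cell classes for an arbitrary
    mannuronate/guluronate ratio mu = M/G, with a brute-force enumeration
    oracle and a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
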