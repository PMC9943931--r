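Package: nnc
Title: Niche-Neutral Continuum Metacommunity Simulation and Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spatially-explicit individual-based simulation of metacommunity
    dynamics along a niche-neutral continuum. Local communities of fixed size
    sit on a torus lattice; individuals disperse to the eight nearest
    neighbouring communities, speciate by point mutation with niche
    conservatism, and experience environmental filtering of immigration
    success through Gaussian niches. The package provides the landscape and
    species-pool generators, the forward simulation engine with a coupled
    monodominance/infinite-diversity convergence test, functional-diversity
    statistics (Simpson and Rao effective numbers, Gaussian niche overlap,
    functional uniqueness and redundancy), a linear-ordination core
    (Hellinger transform, orthogonal environmental polynomials, partial
    redundancy analysis, permutation tests, forward selection), spatial
    statistics (PCNM eigenfunctions, Moran's I correlograms, Mantel tests),
    the variation-partitioning and hierarchical habitat-structure
    diagnostics, and a scenario workbench reproducing the full 825-scenario
    experimental design at full or reduced scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
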