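Package: veintop
Title: Topological Phenotyping of Planar Reticulate Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the architecture of planar reticulate
    vascular networks such as the minor venation of angiosperm leaves.
    Decomposes a weighted planar network into its hierarchy of nested
    loops (the nesting tree), computes nesting ratios, nesting numbers
    and topological tapering lengths alongside classical geometric
    venation metrics, assembles them into an eight-metric venation
    fingerprint, compares networks with a Kolmogorov-Smirnov distance on
    nesting-ratio distributions, identifies specimens from fragments with
    linear discriminant analysis, and simulates minor-vein development
    with a stochastic loop-subdivision growth model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    MASS,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
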