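Package: divfacets
Title: Multi-Facet Biodiversity Analysis on Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing taxonomic, functional and phylogenetic
    diversity of species assemblages on a regular spatial grid. Builds
    presence/absence matrices from range polygons refined by elevation
    limits and habitat types, computes species richness, convex-hull
    functional richness and Faith's phylogenetic diversity, standardizes
    the latter two against richness-preserving Curveball null models, and
    relates diversity facets to climate, land-use and topography
    predictors with spatially explicit generalized least squares,
    Dutilleul's modified t-test and Kruskal-Wallis/Dunn group
    comparisons. A seeded synthetic-landscape generator produces complete
    study systems (environmental surfaces, range maps, traits,
    phylogenies, predictors) for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    ape,
    polyclip,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    sp,
    picante,
    vegan,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
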