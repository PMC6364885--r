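Package: cropshift
Title: Regional Shifts in Crop Taxonomic and Phylogenetic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying temporal change in the taxonomic and
    phylogenetic diversity of crops grown within and among subcontinental
    regions, from long-format area-harvested panels in the FAOSTAT dialect.
    Computes per-region yearly species richness, Gini-Simpson diversity,
    Faith's phylogenetic diversity and Rao's quadratic entropy (with a
    one-species-per-commodity-group randomization), dates crop phylogenies by
    even node-age interpolation between calibrated nodes, fits six candidate
    temporal models including a bootstrapped two-breakpoint piecewise
    regression selected by AIC, derives breakpoint indicators (onset,
    duration, post-break rate) with cross-metric 1:1 hypothesis tests, and
    measures among-region homogenization through Bray-Curtis dissimilarity,
    NMDS ordination, PERMANOVA and within-year similarity trends. Includes
    synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vegan,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    picante,
    car,
    withr,
    jsonlite
Config/testthat/edition: 3
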