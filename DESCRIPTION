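Package: phyrange
Title: Phylogenetically Controlled Analysis of Geographic Range Size and Rarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing geographic range size and rarity between plant
    lifeforms (epiphytic versus terrestrial) while accounting for shared
    ancestry. Implements occurrence-record cleaning for georeferenced and
    non-georeferenced herbarium data, three range-size metrics (native
    botanical-country counts, specimen counts, and extent of occurrence as the
    geodesic area of the minimum convex polygon), a regression layer built from
    first principles (log-scale ordinary least squares, quasi-Poisson
    generalized linear models fitted by iteratively reweighted least squares,
    and phylogenetic generalized least squares with Pagel's lambda estimated by
    profile maximum likelihood), percentage-difference effect sizes,
    aggregation of estimates across sets of phylogenetic trees, rarity
    classification against extent-of-occurrence and specimen-count thresholds,
    and a synthetic-data generator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools,
    withr
Config/testthat/edition: 3
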