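Package: gerontome
Title: Systematic Analysis of Aging-Related Genes and Age-Related Diseases
Version: 0.1.0
Authors@R:
    person("Maglab", "Reanalysis", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for systems-level analysis of the gerontome, the collection
    of genes known to modulate aging and longevity. Builds pro- and
    anti-longevity gene sets per model organism, filters age-related disease
    (ARD) gene catalogs, corrects for publication bias, tests aging-disease
    overlaps with one-sided hypergeometric (Fisher) tests under configurable
    background policies, expands seed sets through protein-interaction and
    co-expression networks, characterizes common aging-and-disease (CAD)
    genes (disease frequency, hub degree, dN/dS), ranks candidate
    lifespan-extending drugs from drug-gene interaction tables with a
    direction-aware hypergeometric score, and generates a fully synthetic
    benchmark (heavy-tailed interactome, publication counts correlated with
    degree, planted overlaps and drugs) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
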