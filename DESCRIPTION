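Package: cpord
Title: Canonical Phylogenetic Ordination of Species Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained ordination tools for partitioning interspecific
    trait variation between phylogenetic ancestry and present-day ecology.
    Implements redundancy analysis (RDA) with Monte-Carlo permutation tests,
    canonical phylogenetic ordination (CPO) on binary clade-membership
    matrices derived from rooted trees, permutation-based forward selection
    of explanatory variables, and partial-RDA variance partitioning into
    phylogeny-unique, ecology-unique, shared and unexplained fractions.
    Ships a worked example on the reproductive biology of a 17-species
    temperate South American xenodontine snake community, and a
    Brownian-motion trait simulator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
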