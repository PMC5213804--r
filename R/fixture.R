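#' Packaged 17-species snake reproductive dataset
#'
#' The worked example shipped with the package: reproductive and
#' ecological attributes of 17 xenodontine snake species from a temperate
#' South American community (918 adult females across nine genera and six
#' tribes), together with a rooted tribe/genus-level phylogeny over the
#' same species.
#'
#' The trait table carries, per species: tribe, number of mature females
#' examined, reproductive mode (oviparous/viviparous), reproductive
#' frequency (proportion of reproductive females in the breeding season)
#' and its annual/biennial classification, mean fecundity, reproductive
#' potential (value and class) and the substrate-use and habitat-use
#' categories.  One species (*Erythrolamprus poecilogyrus*) is published
#' with a reproductive-potential class ("medium") that disagrees with
#' the classification rule applied to its own fecundity and frequency
#' (8 x 0.6 = 4.8, "low"); the table keeps the published letter and
#' flags the row in `rp_printed_mismatch` instead of correcting it.
#'
#' The tree encodes the groupings that are certain at tribe/genus level:
#' the six tribes and the multi-species genera as labelled clades, the
#' single-species tribe Hydrodynastini as a labelled unary branch, and
#' Hydrodynastini sister to Pseudoboini; the remaining backbone is an
#' unresolved root polytomy.  Branch lengths are absent (clade-membership
#' coding ignores them).  Supply your own Newick to
#' [cpo_analysis()] to use a different hypothesis.
#'
#' @return list with elements `traits` (data frame of species trait
#'   rows), `tree` (`"phylo"`), and `provenance` (character notes).
#' @examples
#' fx <- snake_fixture()
#' nrow(fx$traits) # 17
#' sum(fx$traits$n_individuals) # 918
#' @export
snake_fixture <- function() {
  traits <- read_species_traits(
    system.file("extdata", "snake_traits.csv", package = "cpord", mustWork = TRUE)
  )
  tree <- parse_newick(paste(readLines(
    system.file("extdata", "snake_tree.nwk", package = "cpord", mustWork = TRUE)
  ), collapse = ""))
  list(
    traits = traits,
    tree = tree,
    provenance = c(
      "Species-level reproductive and ecological attributes of a 17-species",
      "temperate South American xenodontine snake community (918 mature females).",
      "Tree: tribe/genus-level groupings with unresolved backbone (root polytomy);",
      "single-species tribe Hydrodynastini carried as a labelled unary branch.",
      "The E. poecilogyrus RP class is kept as published and flagged",
      "rp_printed_mismatch (rule-derived class differs)."
    )
  )
}
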