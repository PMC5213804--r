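#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' @param n_species number of leaves (at least 2).
#' @param birth_rate speciation rate per lineage per unit time.
#' @param seed integer seed; same seed, same tree.
#' @return a `"phylo"` tree with `n_species` leaves labelled
#'   `sp01, sp02, ...`, branch lengths in time units, all root-to-tip
#'   distances equal.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop("need at least 2 species")
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
    tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
    tree
  })
}

#' Evolve a continuous trait by Brownian motion along a tree
#'
#' Each branch adds an independent normal increment with variance
#' `sigma^2 * branch length`; leaf values are therefore jointly normal
#' with covariance `sigma^2` times the shared path length from the root.
#'
#' @param tree a `"phylo"` tree with branch lengths.
#' @param sigma diffusion standard deviation per unit branch length.
#' @param root_value trait value at the root.
#' @param seed integer seed, or `NULL`.
#' @return named numeric vector of leaf values (in `tip.label` order).
#' @export
evolve_bm <- function(tree, sigma = 1, root_value = 0, seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- length(tree$tip.label)
  with_seed(seed, {
    edge <- tree$edge
    # cladewise order: parents appear before their children
    edge_ord <- stats::reorder(tree, "cladewise")$edge
    len <- tree$edge.length[match(
      paste(edge_ord[, 1], edge_ord[, 2]),
      paste(edge[, 1], edge[, 2])
    )]
    val <- numeric(n + tree$Nnode)
    val[n + 1L] <- root_value
    for (e in seq_len(nrow(edge_ord))) {
      val[edge_ord[e, 2]] <- val[edge_ord[e, 1]] + rnorm(1, 0, sigma * sqrt(len[e]))
    }
    stats::setNames(val[seq_len(n)], tree$tip.label)
  })
}

#' Simulate a species-trait dataset with known phylogenetic and
#' ecological signal
#'
#' Generates a Yule tree, assigns each species an ecological category
#' (either concentrated on subtrees, so that ecology is confounded with
#' phylogeny, or i.i.d. uniformly), and builds latent trait variables
#'
#' \deqn{z = a \cdot \mathrm{std}(BM) + b \cdot \mathrm{std}(effect) + \epsilon,
#'   \quad \epsilon \sim N(0, \sigma_n^2)}
#'
#' where BM is a Brownian-motion trait on the tree, the category effect
#' gives each ecological class its own level, and both signal components
#' are standardised so the latent variance decomposes as
#' `a^2 : b^2 : noise_sd^2`.  Continuous traits are affine transforms of
#' such latents; categorical traits threshold further latents at
#' quantiles.  The output mimics a reproductive trait table: mean
#' fecundity (positive continuous), mode (binary categorical), a
#' frequency proportion with its annual/biennial class, the derived
#' reproductive potential, and the ecological category as `substrate`.
#'
#' Defaults mirror the packaged snake community: 17 species, a dominant
#' phylogenetic signal (`phylo_weight = 1`) with a weaker ecological
#' effect (`eco_weight = 0.5`), two ecological categories (aquatic-like
#' vs not) concentrated on subtrees, and unit residual noise.
#'
#' @param n_species number of species (at least 4).
#' @param birth_rate Yule speciation rate.
#' @param phylo_weight weight `a` of the Brownian (phylogenetic) signal.
#' @param eco_weight weight `b` of the ecological category effect.
#' @param noise_sd standard deviation of the i.i.d. residual noise.
#' @param n_numeric_traits number of continuous traits (>= 1; the first
#'   becomes mean fecundity).
#' @param n_categorical_traits number of thresholded binary traits
#'   (>= 1; the first becomes reproductive mode).
#' @param n_eco_categories number of ecological categories (>= 2).
#' @param eco_clustered_on_tree concentrate categories on subtrees?
#' @param seed integer seed (required, for reproducibility).
#' @return list of class `"cpo_sim"` with elements `tree`, `traits`
#'   (species trait table usable by [response_matrix()] and
#'   [ecology_matrix()] with `vars = "substrate"`), `eco` (the centred
#'   ecology [coded_matrix()]), `latents` (species x latent matrix) and
#'   `truth` (list: the weights, noise, category assignment and the
#'   realized variance shares of each latent).
#' @examples
#' sim <- simulate_dataset(n_species = 12, seed = 7)
#' sim$truth$shares
#' @export
simulate_dataset <- function(n_species = 17, birth_rate = 1,
                             phylo_weight = 1, eco_weight = 0.5, noise_sd = 1,
                             n_numeric_traits = 1, n_categorical_traits = 3,
                             n_eco_categories = 2, eco_clustered_on_tree = TRUE,
                             seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_species < 4) stop("need at least 4 species")
  if (!is.finite(phylo_weight) || !is.finite(eco_weight) ||
    phylo_weight < 0 || eco_weight < 0) {
    stop("weights must be finite and non-negative")
  }
  tree <- simulate_tree(n_species, birth_rate, seed = seed)
  with_seed(seed + 1L, {
    cat_assign <- assign_categories(tree, n_eco_categories, eco_clustered_on_tree)
    eco_levels <- c("aquatic", "terrestrial", "arboreal", "fossorial")[seq_len(n_eco_categories)]
    substrate <- eco_levels[cat_assign]
    # one shared effect direction: each category has its own level
    effect_raw <- seq_len(n_eco_categories)[cat_assign]
    std <- function(v) {
      s <- sd(v)
      if (s < .Machine$double.eps) v - mean(v) else (v - mean(v)) / s
    }
    n_lat <- n_numeric_traits + n_categorical_traits
    latents <- sapply(seq_len(n_lat), function(j) {
      bm <- std(evolve_bm(tree, sigma = 1, root_value = 0))
      phylo_weight * bm + eco_weight * std(effect_raw) + rnorm(n_species, 0, noise_sd)
    })
    rownames(latents) <- tree$tip.label
    colnames(latents) <- paste0("latent", seq_len(n_lat))

    mf <- pmax(1, 10 + 4 * std(latents[, 1]))
    mode <- ifelse(latents[, n_numeric_traits + 1L] >
      quantile(latents[, n_numeric_traits + 1L], 0.7), "viviparous", "oviparous")
    rf_lat <- if (n_categorical_traits >= 2) latents[, n_numeric_traits + 2L] else latents[, 1]
    rf <- round(plogis(std(rf_lat)), 2)
    rp <- reproductive_potential(mf, rf)
    traits <- data.frame(
      species_id = tree$tip.label,
      tribe = NA_character_,
      n_individuals = NA_integer_,
      mode = mode,
      rf = rf,
      freq_class = classify_frequency(rf),
      mf = mf,
      rp_value = rp$rp_value,
      rp_class = rp$rp_class,
      substrate = substrate,
      habitat = NA_character_,
      stringsAsFactors = FALSE
    )
    eco <- ecology_matrix(traits, vars = "substrate")
    denom <- phylo_weight^2 + eco_weight^2 + noise_sd^2
    structure(list(
      tree = tree, traits = traits, eco = eco, latents = latents,
      truth = list(
        phylo_weight = phylo_weight, eco_weight = eco_weight,
        noise_sd = noise_sd, category = cat_assign,
        shares = c(
          phylo = phylo_weight^2 / denom,
          eco = eco_weight^2 / denom,
          noise = noise_sd^2 / denom
        )
      )
    ), class = "cpo_sim")
  })
}

# pick k categories: either one subtree per extra category (clustered) or
# i.i.d. uniform; every category is guaranteed at least one species
assign_categories <- function(tree, k, clustered) {
  n <- length(tree$tip.label)
  if (k < 2) stop("need at least 2 ecological categories")
  if (!clustered) {
    repeat {
      a <- sample.int(k, n, replace = TRUE)
      if (length(unique(a)) == k) {
        return(a)
      }
    }
  }
  sets <- node_leafsets(tree)
  internal <- setdiff(seq.int(n + 1L, n + tree$Nnode), n + 1L)
  sizes <- lengths(sets[internal])
  ok <- internal[sizes >= 2 & sizes <= floor(n / 2)]
  ok <- ok[order(-lengths(sets[ok]))]
  assign <- rep(1L, n)
  used <- integer(0)
  ki <- 2L
  for (nd in ok) {
    if (ki > k) break
    leaves <- sets[[nd]]
    if (!length(intersect(leaves, used))) {
      assign[leaves] <- ki
      used <- c(used, leaves)
      ki <- ki + 1L
    }
  }
  if (ki <= k) { # tree too small/unbalanced: fill remaining categories singly
    free <- setdiff(seq_len(n), used)
    for (j in ki:k) {
      assign[free[j - ki + 1L]] <- j
    }
  }
  assign
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
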