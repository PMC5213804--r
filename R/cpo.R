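#' Marginal permutation tests of individual clade variables
#'
#' Fits one single-constraint RDA per clade column and tests it with a
#' Monte-Carlo permutation test; clades are ranked by the fraction of
#' total inertia each explains on its own.  Marginal fractions need not
#' sum to the fit of the joint model.
#'
#' @param Y response [coded_matrix()].
#' @param clades clade-membership matrix (see [clade_indicators()]), or
#'   any explanatory matrix whose columns are to be screened one by one.
#' @param permutations permutations per test.
#' @param seed integer; column `i` uses `seed + i - 1` so the table is
#'   reproducible and each test has its own stream.
#' @return data frame of class `"clade_test_table"` with columns `clade`,
#'   `fraction`, `F`, `p`, `seed`, ordered by decreasing `fraction`.
#' @export
clade_tests <- function(Y, clades, permutations = 999, seed = 1) {
  clades <- as.matrix(clades)
  if (ncol(clades) == 0L) stop("empty clade set")
  rows <- lapply(seq_len(ncol(clades)), function(i) {
    s <- seed + i - 1L
    pt <- rda_permtest(Y, clades[, i, drop = FALSE],
      permutations = permutations, seed = s
    )
    data.frame(
      clade = colnames(clades)[i], fraction = pt$fraction,
      F = pt$observed_f, p = pt$p_value, seed = s
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fraction, out$clade), ]
  rownames(out) <- NULL
  class(out) <- c("clade_test_table", class(out))
  out
}

#' Forward stepwise selection of explanatory variables
#'
#' At each step the candidate adding the most explained inertia (ties
#' broken by label order) is tested with a permutation test conditioned
#' on the variables already selected; it enters if its conditional
#' p-value is at most `alpha`, otherwise selection stops.  An empty
#' selection is a valid result.
#'
#' @param Y response [coded_matrix()].
#' @param candidates matrix of candidate explanatory columns.
#' @param alpha significance level for admission (default 0.05).
#' @param permutations permutations per conditional test.
#' @param seed integer; step `s` uses `seed + s - 1`.
#' @param scheme permutation scheme for the conditioned steps, see
#'   [rda_permtest()].
#' @return object of class `"forward_selection"`: data frame with one row
#'   per *selected* step (`variable`, `added_fraction` of total inertia,
#'   `cum_fraction`, `F`, `p`, `seed`) plus attributes `selected`
#'   (labels in order) and `stopped_at` (the first rejected candidate's
#'   row, or `NULL` if all candidates entered).
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, permutations = 999,
                           seed = 1, scheme = c("reduced_model", "unrestricted")) {
  scheme <- match.arg(scheme)
  stopifnot(alpha > 0, alpha < 1)
  candidates <- as.matrix(candidates)
  labels <- colnames(candidates) %||% paste0("V", seq_len(ncol(candidates)))
  sel <- integer(0)
  steps <- list()
  stopped <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    rest <- setdiff(seq_len(ncol(candidates)), sel)
    if (!length(rest)) break
    base <- if (length(sel)) {
      rda_fit(Y, candidates[, sel, drop = FALSE])$fraction
    } else {
      0
    }
    gains <- vapply(rest, function(j) {
      rda_fit(Y, candidates[, c(sel, j), drop = FALSE])$fraction - base
    }, numeric(1))
    ord <- order(-gains, labels[rest]) # ties: lexicographic label order
    j <- rest[ord[1]]
    s <- seed + step - 1L
    pt <- rda_permtest(Y, candidates[, j, drop = FALSE],
      condition = if (length(sel)) candidates[, sel, drop = FALSE] else NULL,
      permutations = permutations, seed = s, scheme = scheme
    )
    row <- data.frame(
      variable = labels[j], added_fraction = gains[ord[1]],
      cum_fraction = base + gains[ord[1]], F = pt$observed_f,
      p = pt$p_value, seed = s
    )
    if (pt$p_value <= alpha) {
      sel <- c(sel, j)
      steps[[length(steps) + 1L]] <- row
    } else {
      stopped <- row
      break
    }
  }
  out <- if (length(steps)) {
    do.call(rbind, steps)
  } else {
    data.frame(
      variable = character(0), added_fraction = numeric(0),
      cum_fraction = numeric(0), F = numeric(0), p = numeric(0),
      seed = integer(0)
    )
  }
  rownames(out) <- NULL
  structure(out,
    selected = out$variable, stopped_at = stopped, alpha = alpha,
    class = c("forward_selection", class(out))
  )
}

#' Two-set variance partition via nested RDA fits
#'
#' Splits the variation of `Y` into the component explained only by the
#' first explanatory set (A, e.g. phylogeny), only by the second (B,
#' e.g. ecology), by both jointly but inseparably (shared, C), and the
#' unexplained remainder (U), from three fits:
#' `A = R_joint - R_eco`, `B = R_joint - R_phy`,
#' `C = R_eco + R_phy - R_joint`, `U = 1 - R_joint`.  All components are
#' fractions of the total inertia of `Y`, so `A + B + C + U = 1`
#' identically; `C` can be negative for pathological data and is reported
#' as computed, never clamped.  The unique fractions equal the
#' explained fractions of the corresponding partial RDAs
#' (`rda_fit(Y, X, condition = Z)`), a property the test suite asserts.
#'
#' @param Y response [coded_matrix()].
#' @param X_phylo explanatory set treated as "phylogeny" (component A).
#' @param X_eco explanatory set treated as "ecology" (component B).
#' @return object of class `"cpo_varpart"`: list with `A` (unique
#'   phylogeny), `B` (unique ecology), `C` (shared), `U` (unexplained),
#'   `R_phy`, `R_eco`, `R_joint`.
#' @export
variance_partition <- function(Y, X_phylo, X_eco) {
  r_phy <- rda_fit(Y, X_phylo)$fraction
  r_eco <- rda_fit(Y, X_eco)$fraction
  r_joint <- rda_fit(Y, cbind(as.matrix(X_phylo), as.matrix(X_eco)))$fraction
  structure(list(
    A = r_joint - r_eco, B = r_joint - r_phy,
    C = r_eco + r_phy - r_joint, U = 1 - r_joint,
    R_phy = r_phy, R_eco = r_eco, R_joint = r_joint
  ), class = "cpo_varpart")
}

#' @export
print.cpo_varpart <- function(x, ...) {
  cat("variance partition (fractions of total inertia)\n")
  cat(sprintf("  A  unique to phylogeny: %6.3f\n", x$A))
  cat(sprintf("  B  unique to ecology:   %6.3f\n", x$B))
  cat(sprintf("  C  shared:              %6.3f\n", x$C))
  cat(sprintf("  U  unexplained:         %6.3f\n", x$U))
  cat(sprintf(
    "  (phylogeny total %.3f, ecology total %.3f, joint %.3f)\n",
    x$R_phy, x$R_eco, x$R_joint
  ))
  invisible(x)
}

#' Full canonical phylogenetic ordination analysis
#'
#' Runs the whole inference pipeline on a species trait table and a
#' rooted phylogeny over the same species:
#' 1. *Ecology RDA*: forward selection over the ecological category
#'    dummies at `eco_alpha`;
#' 2. *CPO*: marginal permutation tests of every candidate clade, then
#'    forward selection of clades at `clade_alpha`;
#' 3. *Partial CPO*: the variance partition between the selected clade
#'    set and the selected ecological variables, plus triplot scores of
#'    the joint model.
#' Stage 3 is skipped (with the report saying so) when either selection
#' comes back empty.
#'
#' The clade stage's default threshold is more liberal than the
#' conventional 0.05 because a single-species clade can never beat the
#' resolution floor of a row-permutation test (`1/n` with the add-one
#' convention; about 0.059 for 17 species), yet such clades are
#' legitimate, often top-ranked candidates; 0.10 admits candidates at
#' the floor while still discarding clearly non-significant clades.
#' Set `clade_alpha = 0.05` for the strict convention.
#'
#' @param traits species trait table (see [response_matrix()]).
#' @param tree a `"phylo"` object whose tip labels match
#'   `traits$species_id` (spaces/underscores interchangeable).
#' @param scaling,frequency response coding, see [response_matrix()].
#' @param eco_vars categorical columns of `traits` used as ecology.
#' @param candidate_clades `"labelled_only"` (default) restricts clade
#'   candidates to nodes with explicit labels (named tribes/genera);
#'   `"all_nodes"` uses every internal node.
#' @param min_clade_size smallest clade admitted as a candidate
#'   (default 1: labelled unary branches are candidates).
#' @param eco_alpha,clade_alpha forward-selection thresholds.
#' @param permutations Monte-Carlo permutations per test.
#' @param seed integer seed; every permutation test derives its own
#'   stream from it (recorded in the tables).
#' @return object of class `"cpo_analysis"`: list with elements
#'   `config`, `response` (coded matrix), `ecology` (stage-1
#'   [forward_select()] result plus the marginal table), `cpo`
#'   (clade marginal table and forward selection), `partition`
#'   (a [variance_partition()] or `NULL`), `joint` (the all-selected
#'   `"crda"` fit or `NULL`) and `triplot` (scores of `joint`).
#' @examples
#' fx <- snake_fixture()
#' res <- cpo_analysis(fx$traits, fx$tree, permutations = 199, seed = 42)
#' res
#' @export
cpo_analysis <- function(traits, tree,
                         scaling = c("covariance", "correlation"),
                         frequency = c("binary", "numeric"),
                         eco_vars = c("substrate", "habitat"),
                         candidate_clades = c("labelled_only", "all_nodes"),
                         min_clade_size = 1,
                         eco_alpha = 0.05, clade_alpha = 0.10,
                         permutations = 999, seed = 1,
                         scheme = c("reduced_model", "unrestricted")) {
  scaling <- match.arg(scaling)
  frequency <- match.arg(frequency)
  candidate_clades <- match.arg(candidate_clades)
  scheme <- match.arg(scheme)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s stage] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  Y <- stage("coding", response_matrix(traits, scaling, frequency))
  E <- if (length(eco_vars)) stage("coding", ecology_matrix(traits, eco_vars)) else NULL
  tree <- stage("coding", align_tree(tree, traits$species_id))
  clades <- stage("coding", clade_indicators(tree,
    min_size = min_clade_size,
    labelled_only = candidate_clades == "labelled_only"
  ))
  # reorder indicator rows (tree tip order) to the trait-table order
  clades <- clades[attr(tree, "trait_order"), , drop = FALSE]
  rownames(clades) <- traits$species_id

  eco_sel <- if (is.null(E)) {
    NULL
  } else {
    stage("ecology", forward_select(Y, E,
      alpha = eco_alpha,
      permutations = permutations, seed = seed, scheme = scheme
    ))
  }
  eco_marginal <- if (is.null(E)) {
    NULL
  } else {
    stage("ecology", clade_tests(Y, E, permutations = permutations, seed = seed + 100L))
  }

  marginal <- stage("cpo", clade_tests(Y, clades,
    permutations = permutations,
    seed = seed + 200L
  ))
  clade_sel <- stage("cpo", forward_select(Y, clades,
    alpha = clade_alpha,
    permutations = permutations, seed = seed + 300L, scheme = scheme
  ))

  partition <- NULL
  joint <- NULL
  triplot <- NULL
  esel <- attr(eco_sel, "selected")
  csel <- attr(clade_sel, "selected")
  if (length(csel) && length(esel)) {
    Xp <- clades[, csel, drop = FALSE]
    Xe <- uncode(E)[, esel, drop = FALSE]
    partition <- stage("pcpo", variance_partition(Y, Xp, Xe))
    joint <- stage("pcpo", rda_fit(Y, cbind(Xe, Xp)))
    triplot <- stage("pcpo", triplot_scores(joint))
  }

  structure(list(
    config = list(
      scaling = scaling, frequency = frequency, eco_vars = eco_vars,
      candidate_clades = candidate_clades, min_clade_size = min_clade_size,
      eco_alpha = eco_alpha, clade_alpha = clade_alpha,
      permutations = permutations, seed = seed, scheme = scheme
    ),
    response = Y,
    ecology = list(selection = eco_sel, marginal = eco_marginal),
    cpo = list(marginal = marginal, selection = clade_sel),
    partition = partition, joint = joint, triplot = triplot
  ), class = "cpo_analysis")
}

# match tree tips to the trait table's species ids (spaces <-> underscores),
# check the one-to-one correspondence, and order tips-agnostically:
# clade_indicators rows follow tree$tip.label, so reorder the tree's tips
# is not needed - instead we permute the indicator rows to the trait order.
align_tree <- function(tree, species_id) {
  tip_norm <- gsub("_", " ", tree$tip.label)
  sp_norm <- gsub("_", " ", species_id)
  if (anyDuplicated(sp_norm)) stop("duplicated species ids in trait table")
  idx <- match(sp_norm, tip_norm)
  if (anyNA(idx)) {
    stop(
      "species missing from tree: ",
      paste(species_id[is.na(idx)], collapse = ", ")
    )
  }
  extra <- setdiff(tip_norm, sp_norm)
  if (length(extra)) {
    stop("tree has tips absent from the trait table: ", paste(extra, collapse = ", "))
  }
  tree$tip.label <- tip_norm
  attr(tree, "trait_order") <- idx
  tree
}

#' @export
print.cpo_analysis <- function(x, ...) {
  cat("canonical phylogenetic ordination analysis\n")
  cat(sprintf(
    "  coding: %s scaling, %s frequency; %d permutations, seed %d\n",
    x$config$scaling, x$config$frequency, x$config$permutations, x$config$seed
  ))
  esel <- attr(x$ecology$selection, "selected")
  if (!is.null(x$ecology$selection)) {
    cat(sprintf(
      "  ecology stage: selected {%s}\n",
      if (length(esel)) paste(esel, collapse = ", ") else ""
    ))
  }
  csel <- attr(x$cpo$selection, "selected")
  cat(sprintf(
    "  clade stage:   selected {%s}\n",
    if (length(csel)) paste(csel, collapse = ", ") else ""
  ))
  if (length(csel)) {
    cat("  clade selection steps:\n")
    df <- as.data.frame(x$cpo$selection)
    df$added_fraction <- round(100 * df$added_fraction, 1)
    df$cum_fraction <- round(100 * df$cum_fraction, 1)
    names(df)[2:3] <- c("added %", "cum %")
    print(df[, 1:5], row.names = FALSE, digits = 3)
  }
  if (!is.null(x$partition)) print(x$partition)
  invisible(x)
}
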