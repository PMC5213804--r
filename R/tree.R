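#' Parse a Newick string into an `ape` phylo tree
#'
#' Thin wrapper around [ape::read.tree()] that insists on a well-formed,
#' semicolon-terminated string, preserves polytomies, internal-node
#' labels and singleton (unary) nodes, and gives a positional error for
#' malformed input.
#'
#' @param text Newick string.
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A,B)AB,C)root;")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) stop("'text' must be a single string")
  if (!grepl(";", text)) stop("malformed Newick: missing terminating ';'")
  depth <- cumsum((strsplit(text, "")[[1]] == "(") - (strsplit(text, "")[[1]] == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    stop(
      "malformed Newick: unbalanced parentheses near position ",
      which(depth < 0)[1] %||% length(depth)
    )
  }
  tree <- tryCatch(ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("malformed Newick: could not be parsed")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  tree
}

#' Serialise a tree back to Newick
#'
#' @param tree a `"phylo"` object.
#' @return Newick string (topology, labels and any branch lengths).
#' @export
serialize_newick <- function(tree) {
  ape::write.tree(tree)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# leaf set under every node (tips + internals), as a list indexed by node number
node_leafsets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  edge <- stats::reorder(tree, "postorder")$edge # children edges before parents
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- i
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]
    chi <- edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  lapply(sets, sort)
}

#' Binary clade-membership matrix from a rooted tree
#'
#' One column per internal node of the tree, with value 1 for the species
#' descending from that node and 0 otherwise - the explanatory matrix of
#' canonical phylogenetic ordination.  The root (an all-ones, hence
#' constant, column) is always uninformative and excluded by default;
#' `min_size = 1` admits single-species clades carried as labelled unary
#' branches (a single-species tribe is a legitimate candidate variable).
#' Columns are labelled with the tree's internal-node labels where
#' present, otherwise `node<k>`.
#'
#' @param tree a `"phylo"` object (e.g. from [parse_newick()]).
#' @param min_size smallest clade (leaf-set size) to keep; default 2.
#' @param exclude_root drop the all-species column? Default `TRUE`.
#' @param labelled_only keep only clades with an explicit node label.
#' @return 0/1 matrix of class `"clade_matrix"` (species x clades) with a
#'   `leafsets` attribute naming each column's members and a `provenance`
#'   attribute recording the source topology and options.
#' @examples
#' cm <- clade_indicators(parse_newick("((A,B)AB,C);"))
#' cm
#' @export
clade_indicators <- function(tree, min_size = 2, exclude_root = TRUE,
                             labelled_only = FALSE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  n <- length(tree$tip.label)
  sets <- node_leafsets(tree)
  root <- n + 1L
  nodes <- setdiff(seq.int(n + 1L, n + tree$Nnode), if (exclude_root) root)
  labs <- tree$node.label %||% rep("", tree$Nnode)
  labs[!nzchar(labs)] <- paste0("node", which(!nzchar(labs)))
  keep <- vapply(nodes, function(nd) {
    sz <- length(sets[[nd]])
    sz >= min_size && sz <= n - 1L
  }, logical(1))
  nodes <- nodes[keep]
  if (labelled_only) {
    lb <- tree$node.label %||% rep("", tree$Nnode)
    nodes <- nodes[nzchar(lb[nodes - n])]
  }
  if (!length(nodes)) stop("no clade satisfies the size/label constraints")
  m <- vapply(nodes, function(nd) {
    v <- numeric(n)
    v[sets[[nd]]] <- 1
    v
  }, numeric(n))
  rownames(m) <- tree$tip.label
  colnames(m) <- labs[nodes - n]
  structure(m,
    leafsets = lapply(nodes, function(nd) tree$tip.label[sets[[nd]]]),
    provenance = list(
      newick = ape::write.tree(tree),
      min_size = min_size, exclude_root = exclude_root,
      labelled_only = labelled_only
    ),
    class = c("clade_matrix", class(m))
  )
}

#' @export
print.clade_matrix <- function(x, ...) {
  cat(sprintf("clade-membership matrix: %d species x %d clades\n", nrow(x), ncol(x)))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Look up the clade column matching a set of species
#'
#' @param clades a `"clade_matrix"` from [clade_indicators()].
#' @param leaf_set character vector of species ids.
#' @return the matching column label, or `NA_character_` when no clade
#'   has exactly that membership (absence is a value, not an error).
#' @export
clade_column <- function(clades, leaf_set) {
  target <- sort(as.character(leaf_set))
  sets <- attr(clades, "leafsets")
  hit <- which(vapply(sets, function(s) identical(sort(s), target), logical(1)))
  if (length(hit)) colnames(clades)[hit[1]] else NA_character_
}
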