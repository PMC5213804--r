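#' Construct a coded (centred, optionally standardised) numeric matrix
#'
#' The common currency of the ordination functions: a numeric matrix with
#' species in rows, variables in columns, every column centred to mean
#' zero, and (optionally) scaled to unit variance.  Dummy blocks for a
#' k-level categorical variable keep all k columns (full redundant
#' coding), so before centring each block sums to one across its columns;
#' the ordination core handles the resulting rank deficiency by
#' pseudo-inverse projection.
#'
#' @param x numeric matrix or data frame with row names (species ids).
#' @param standardize scale every non-constant column to unit variance?
#' @param coding optional list recording how the columns were built
#'   (kept as an attribute, used by print methods and report export).
#' @return a matrix of class `"coded_matrix"` with attributes
#'   `centered`, `standardized` and `coding`.
#' @examples
#' m <- coded_matrix(cbind(a = c(1, 2, 3), b = c(0, 1, 0)))
#' colMeans(m)  # all zero
#' @export
coded_matrix <- function(x, standardize = FALSE, coding = list()) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  x <- scale(x, center = TRUE, scale = FALSE)
  if (standardize) {
    s <- apply(x, 2, sd)
    s[s < .Machine$double.eps] <- 1 # constant columns stay constant
    x <- sweep(x, 2, s, "/")
  }
  attr(x, "scaled:center") <- NULL
  structure(x,
    centered = TRUE, standardized = standardize, coding = coding,
    class = c("coded_matrix", class(x))
  )
}

#' @export
print.coded_matrix <- function(x, ...) {
  cat(sprintf(
    "coded matrix: %d species x %d variables (%s)\n",
    nrow(x), ncol(x),
    if (isTRUE(attr(x, "standardized"))) "correlation scaling" else "covariance scaling"
  ))
  print(unclass(x)[, , drop = FALSE], digits = 3, ...)
  invisible(x)
}

# strip class/attrs for internal numeric work
uncode <- function(x) {
  x <- unclass(x)
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  x
}

#' Write a coded (or clade) matrix to CSV with row labels
#'
#' @param x matrix with row names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  df <- data.frame(species = rownames(x), uncode(as.matrix(x)), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# dummy-code a character/factor vector into a 0/1 matrix, one column per level
dummy_block <- function(f, levels = sort(unique(as.character(f)))) {
  f <- as.character(f)
  bad <- setdiff(unique(f), levels)
  if (length(bad)) stop("unknown category label(s): ", paste(bad, collapse = ", "))
  m <- sapply(levels, function(l) as.numeric(f == l))
  if (!is.matrix(m)) m <- matrix(m, nrow = length(f), dimnames = list(NULL, levels))
  m
}
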