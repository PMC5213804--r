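#' Fit a (partial) redundancy analysis
#'
#' Redundancy analysis regresses every column of a centred response
#' matrix `Y` on the explanatory matrix `X` by least squares and performs
#' a PCA of the fitted values: the canonical eigenvalues decompose the
#' explained inertia (sum of response column variances) and their total,
#' divided by the total inertia of `Y`, is the explained fraction.  With
#' a condition (covariable) matrix `W`, both `Y` and `X` are first
#' replaced by their residuals from projection on `W` (partial RDA);
#' explained fractions of partial fits are reported against the total
#' inertia of the *original* `Y`, so that unique, shared and unexplained
#' components of a variance partition add to one.
#'
#' Explanatory blocks may be rank deficient (full redundant dummy
#' coding is expected); the projection uses the singular value
#' decomposition with a relative tolerance of `1e-8`, and the number of
#' constrained dimensions `q` is the numerical rank.
#'
#' @param Y response matrix (species x traits); a [coded_matrix()] or any
#'   numeric matrix with row names.  Centred internally in any case.
#' @param X explanatory matrix, same rows (and row order) as `Y`.
#' @param condition optional covariable matrix to partial out.
#' @return an object of class `"crda"`: a list with elements
#'   `tot_chi` (total inertia of the original centred `Y`), `cond_chi`
#'   (inertia absorbed by the condition), `constrained_chi`,
#'   `resid_chi`, `fraction` (= `constrained_chi / tot_chi`), `eig`
#'   (non-increasing canonical eigenvalues summing to `constrained_chi`),
#'   `q` (rank of constraints), `p_cond` (rank of condition),
#'   `df_residual`, `n`, `scores` (see [triplot_scores()]) and the
#'   centred input matrices.
#' @seealso [pseudo_f()], [rda_permtest()], [axis_fraction()],
#'   [triplot_scores()]
#' @examples
#' fx <- snake_fixture()
#' Y <- response_matrix(fx$traits, scaling = "covariance")
#' E <- ecology_matrix(fx$traits)
#' fit <- rda_fit(Y, E[, "aquatic", drop = FALSE])
#' fit
#' @export
rda_fit <- function(Y, X, condition = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) < 3L) stop("need at least 3 rows")
  if (nrow(X) != nrow(Y)) stop("'Y' and 'X' must have the same number of rows")
  if (!is.null(rownames(Y)) && !is.null(rownames(X)) &&
    !identical(rownames(Y), rownames(X))) {
    stop("row labels of 'Y' and 'X' are not aligned")
  }
  if (!is.null(condition)) {
    condition <- as.matrix(condition)
    if (nrow(condition) != nrow(Y)) stop("'condition' rows must match 'Y'")
    if (!is.null(rownames(Y)) && !is.null(rownames(condition)) &&
      !identical(rownames(Y), rownames(condition))) {
      stop("row labels of 'Y' and 'condition' are not aligned")
    }
  }
  n <- nrow(Y)
  nu <- n - 1 # inertia denominator
  Yc <- scale(uncode(Y), center = TRUE, scale = FALSE)
  Xc <- scale(uncode(X), center = TRUE, scale = FALSE)
  xbar <- attr(Xc, "scaled:center")
  attr(Yc, "scaled:center") <- NULL
  attr(Xc, "scaled:center") <- NULL
  tot_chi <- sum(Yc^2) / nu
  if (tot_chi < .Machine$double.eps) stop("zero total inertia in 'Y'")

  cond_chi <- 0
  p_cond <- 0L
  Yw <- Yc
  Xw <- Xc
  if (!is.null(condition)) {
    Wc <- scale(uncode(condition), center = TRUE, scale = FALSE)
    pw <- orth_basis(Wc)
    p_cond <- ncol(pw)
    fitW <- pw %*% crossprod(pw, Yc)
    cond_chi <- sum(fitW^2) / nu
    Yw <- Yc - fitW
    Xw <- Xc - pw %*% crossprod(pw, Xc)
  }

  bas <- orth_basis(Xw, ref = svd(Xc, nu = 0, nv = 0)$d[1])
  q <- ncol(bas)
  fitted <- if (q > 0L) bas %*% crossprod(bas, Yw) else matrix(0, n, ncol(Yw))
  constrained_chi <- sum(fitted^2) / nu
  resid_chi <- sum((Yw - fitted)^2) / nu
  df_residual <- n - 1L - q - p_cond

  sv <- svd(fitted)
  pos <- sv$d > max(sv$d[1], 0) * 1e-12
  eig <- (sv$d[pos]^2) / nu
  axes <- if (length(eig)) paste0("CAP", seq_along(eig)) else character(0)
  u <- sv$u[, pos, drop = FALSE] # unit site axes
  dimnames(u) <- list(rownames(Y), axes)
  # scaling-2 style scores: response loadings carry the eigenvalue scale
  sites_lc <- sweep(u, 2, sv$d[pos], "*") # constrained sample scores
  sites_wa <- Yw %*% sv$v[, pos, drop = FALSE] # sample scores from response
  dimnames(sites_wa) <- list(rownames(Y), axes)
  resp <- sv$v[, pos, drop = FALSE] %*% diag(sv$d[pos] / sqrt(nu), sum(pos))
  dimnames(resp) <- list(colnames(Y), axes)
  biplot <- if (q > 0L) {
    b <- suppressWarnings(cor(Xc, sites_lc))
    b[is.na(b)] <- 0
    dimnames(b) <- list(colnames(X), axes)
    b
  } else {
    NULL
  }

  structure(list(
    call = match.call(),
    n = n, q = q, p_cond = p_cond,
    tot_chi = tot_chi, cond_chi = cond_chi,
    constrained_chi = constrained_chi, resid_chi = resid_chi,
    fraction = constrained_chi / tot_chi,
    eig = eig, df_residual = df_residual,
    scores = list(sites = sites_wa, sites_lc = sites_lc, species = resp, biplot = biplot),
    Y = Yc, X = Xc, xbar = xbar, W = if (is.null(condition)) NULL else Wc
  ), class = "crda")
}

# orthonormal basis of the column space, rank-revealing (relative tol 1e-8).
# `ref` anchors the tolerance to a pre-residualisation scale so that a
# matrix annihilated by conditioning keeps no noise directions.
orth_basis <- function(M, tol = 1e-8, ref = NULL) {
  if (ncol(M) == 0L) {
    return(matrix(0, nrow(M), 0))
  }
  sv <- svd(M)
  keep <- sv$d > max(ref %||% sv$d[1], sv$d[1], 0) * tol
  sv$u[, keep, drop = FALSE]
}

#' Pseudo-F statistic of a fitted RDA
#'
#' The permutation-test statistic of constrained ordination: mean
#' explained inertia per constrained dimension over mean residual inertia
#' per residual degree of freedom,
#' `F = (explained / q) / (residual / df_residual)` with
#' `df_residual = n - 1 - q - p_cond`.
#'
#' @param object a `"crda"` fit.
#' @return the pseudo-F value.
#' @export
pseudo_f <- function(object) {
  stopifnot(inherits(object, "crda"))
  if (object$df_residual < 1L) stop("no residual degrees of freedom")
  (object$constrained_chi / object$q) / (object$resid_chi / object$df_residual)
}

#' Cumulative share of variation on the first k canonical axes
#'
#' With `denominator = "canonical"` (the default) the share is of the
#' canonical (fitted) variation, i.e. the sum of all canonical
#' eigenvalues; with `"total"` it is of the total inertia of the
#' response, so it measures how much of *all* trait variation the
#' leading constrained axes carry.  Reports of the form "the first two
#' axes explained x%" use either convention in the literature, so both
#' are offered.
#'
#' @param object a `"crda"` fit.
#' @param k number of leading axes; clamped to the number available.
#' @param denominator `"canonical"` or `"total"`.
#' @return a proportion in (0, 1].
#' @export
axis_fraction <- function(object, k, denominator = c("canonical", "total")) {
  stopifnot(inherits(object, "crda"), k >= 1)
  denominator <- match.arg(denominator)
  k <- min(k, length(object$eig))
  den <- if (denominator == "canonical") sum(object$eig) else object$tot_chi
  sum(object$eig[seq_len(k)]) / den
}

#' Monte-Carlo permutation test for (partial) RDA
#'
#' Tests the null hypothesis that `X` explains no more of `Y` than chance
#' by recomputing the pseudo-F statistic under random row permutations.
#' Without covariables the rows of `Y` are permuted freely; with
#' covariables the default permutes residuals of the reduced
#' (covariable-only) model and adds them back onto the covariable fit -
#' the accepted scheme for conditioned ordination tests - while
#' `scheme = "unrestricted"` permutes the raw rows.  The p-value uses the
#' add-one convention `(n_as_extreme + 1) / (permutations + 1)`.
#'
#' @param Y,X,condition as in [rda_fit()].
#' @param permutations number of random permutations.
#' @param seed integer seed making the test reproducible; `NULL` leaves
#'   the random-number state alone.
#' @param scheme `"reduced_model"` (default, only relevant with a
#'   condition) or `"unrestricted"`.
#' @return an object of class `"crda_perm"`: list with `observed_f`,
#'   `fraction`, `permutations`, `n_as_extreme`, `p_value`, `seed`,
#'   `scheme`.
#' @examples
#' fx <- snake_fixture()
#' Y <- response_matrix(fx$traits, scaling = "covariance")
#' E <- ecology_matrix(fx$traits)
#' rda_permtest(Y, E[, "aquatic", drop = FALSE], permutations = 199, seed = 1)
#' @export
rda_permtest <- function(Y, X, condition = NULL, permutations = 999, seed = NULL,
                         scheme = c("reduced_model", "unrestricted")) {
  scheme <- match.arg(scheme)
  stopifnot(permutations >= 1)
  fit <- rda_fit(Y, X, condition)
  obs <- pseudo_f(fit)
  n <- fit$n
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  Yc <- fit$Y
  # permutation engine avoids re-validating inputs: work on centred copies
  perm_f <- if (is.null(condition)) {
    bas <- orth_basis(fit$X)
    q <- max(fit$q, 1L)
    dfr <- fit$df_residual
    function() {
      Yp <- Yc[sample.int(n), , drop = FALSE]
      fitv <- bas %*% crossprod(bas, Yp)
      expl <- sum(fitv^2)
      res <- sum((Yp - fitv)^2)
      (expl / q) / (res / dfr)
    }
  } else {
    pw <- orth_basis(fit$W)
    fitW <- pw %*% crossprod(pw, Yc)
    resW <- Yc - fitW
    Xw <- fit$X - pw %*% crossprod(pw, fit$X)
    bas <- orth_basis(Xw, ref = svd(fit$X, nu = 0, nv = 0)$d[1])
    q <- max(fit$q, 1L)
    dfr <- fit$df_residual
    function() {
      Yp <- if (scheme == "reduced_model") {
        fitW + resW[sample.int(n), , drop = FALSE]
      } else {
        Yc[sample.int(n), , drop = FALSE]
      }
      Yw <- Yp - pw %*% crossprod(pw, Yp)
      fitv <- bas %*% crossprod(bas, Yw)
      expl <- sum(fitv^2)
      res <- sum((Yw - fitv)^2)
      (expl / q) / (res / dfr)
    }
  }
  stats_perm <- vapply(seq_len(permutations), function(i) perm_f(), numeric(1))
  eps <- sqrt(.Machine$double.eps) * max(1, abs(obs))
  n_extreme <- sum(stats_perm >= obs - eps)
  structure(list(
    observed_f = obs, fraction = fit$fraction,
    permutations = permutations, n_as_extreme = n_extreme,
    p_value = (n_extreme + 1) / (permutations + 1),
    seed = seed, scheme = scheme
  ), class = "crda_perm")
}

#' @export
print.crda_perm <- function(x, ...) {
  cat(sprintf(
    "permutation test: F = %.3f, p = %.4g (%d permutations, %s scheme)\n",
    x$observed_f, x$p_value, x$permutations,
    x$scheme
  ))
  invisible(x)
}
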