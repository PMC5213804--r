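#' @export
print.crda <- function(x, ...) {
  cat("Redundancy analysis", if (x$p_cond > 0) "(partial)", "\n")
  cat(sprintf(
    "  %d species, %d constrained dimension(s)%s\n", x$n, x$q,
    if (x$p_cond > 0) sprintf(", %d conditioned dimension(s)", x$p_cond) else ""
  ))
  cat(sprintf(
    "  total inertia %.4f, constrained %.4f (%.1f%%), residual %.4f\n",
    x$tot_chi, x$constrained_chi, 100 * x$fraction, x$resid_chi
  ))
  if (x$p_cond > 0) {
    cat(sprintf("  conditioned inertia %.4f (%.1f%%)\n", x$cond_chi, 100 * x$cond_chi / x$tot_chi))
  }
  invisible(x)
}

#' @export
summary.crda <- function(object, ...) {
  structure(list(
    fit = object,
    f = pseudo_f(object),
    eig = object$eig,
    cum_axis = cumsum(object$eig) / sum(object$eig)
  ), class = "summary.crda")
}

#' @export
print.summary.crda <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  pseudo-F(%d, %d) = %.3f\n", x$fit$q, x$fit$df_residual, x$f))
  if (length(x$eig)) {
    cat("  canonical eigenvalues:\n")
    tab <- rbind(eigenvalue = x$eig, `cumulative share` = x$cum_axis)
    colnames(tab) <- names(x$eig) %||% paste0("CAP", seq_along(x$eig))
    print(round(tab, 4))
  }
  invisible(x)
}

#' Regression coefficients of the underlying multivariate fit
#'
#' Minimum-norm least-squares coefficients mapping the centred
#' explanatory matrix to the fitted response (pseudo-inverse solution,
#' well defined under redundant dummy coding).
#'
#' @param object a `"crda"` fit.
#' @param ... unused.
#' @return matrix (explanatory variables x response variables).
#' @export
coef.crda <- function(object, ...) {
  Xw <- if (object$p_cond > 0) {
    pw <- orth_basis(object$W)
    object$X - pw %*% crossprod(pw, object$X)
  } else {
    object$X
  }
  Yw <- if (object$p_cond > 0) {
    pw <- orth_basis(object$W)
    object$Y - pw %*% crossprod(pw, object$Y)
  } else {
    object$Y
  }
  sv <- svd(Xw)
  keep <- sv$d > max(svd(object$X, nu = 0, nv = 0)$d[1], sv$d[1], 0) * 1e-8
  b <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], Yw) / sv$d[keep])
  dimnames(b) <- list(colnames(object$X), colnames(object$Y))
  b
}

#' @export
fitted.crda <- function(object, ...) {
  Yw <- object$Y
  Xw <- object$X
  if (object$p_cond > 0) {
    pw <- orth_basis(object$W)
    Yw <- Yw - pw %*% crossprod(pw, Yw)
    Xw <- Xw - pw %*% crossprod(pw, Xw)
  }
  bas <- orth_basis(Xw, ref = svd(object$X, nu = 0, nv = 0)$d[1])
  f <- bas %*% crossprod(bas, Yw)
  dimnames(f) <- dimnames(object$Y)
  f
}

#' Predict trait values for new explanatory rows
#'
#' @param object a `"crda"` fit.
#' @param newdata matrix with the same explanatory columns as the fit
#'   (on the original, uncentred scale); if missing, the fitted values
#'   for the training species are returned.
#' @param ... unused.
#' @return matrix of predicted (centred-scale) response values.
#' @export
predict.crda <- function(object, newdata, ...) {
  if (missing(newdata)) {
    return(fitted(object))
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X)) stop("'newdata' must match the explanatory columns")
  newc <- sweep(newdata, 2, object$xbar, "-") # centre by the training means
  newc %*% coef(object)
}

#' @export
residuals.crda <- function(object, ...) {
  Yw <- object$Y
  if (object$p_cond > 0) {
    pw <- orth_basis(object$W)
    Yw <- Yw - pw %*% crossprod(pw, Yw)
  }
  r <- Yw - fitted(object)
  dimnames(r) <- dimnames(object$Y)
  r
}

#' Triplot scores of a fitted RDA
#'
#' Species points, response-variable arrows and constraint arrows in the
#' plane of the canonical axes, in correlation-style (scaling 2) form:
#' the cosine of the angle between two arrows approximates the sign and
#' strength of the correlation between the variables they represent.
#'
#' @param object a `"crda"` fit.
#' @param axes which two (or more) canonical axes to return.
#' @return list with matrices `species_points` (sample scores),
#'   `response_arrows` and `constraint_arrows`.
#' @export
triplot_scores <- function(object, axes = 1:2) {
  stopifnot(inherits(object, "crda"))
  axes <- axes[axes <= length(object$eig)]
  list(
    species_points = object$scores$sites[, axes, drop = FALSE],
    response_arrows = object$scores$species[, axes, drop = FALSE],
    constraint_arrows = object$scores$biplot[, axes, drop = FALSE]
  )
}

#' Triplot of a fitted RDA
#'
#' Species as points, response variables as solid arrows, constraints as
#' dashed arrows; arrows pointing the same way are positively correlated.
#'
#' @param x a `"crda"` fit.
#' @param axes two canonical axes to display.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.crda <- function(x, axes = 1:2, ...) {
  sc <- triplot_scores(x, axes)
  if (ncol(sc$species_points) < 2) stop("need at least two canonical axes to plot")
  all_x <- rbind(sc$species_points, sc$response_arrows, sc$constraint_arrows)
  graphics::plot(sc$species_points,
    xlim = range(all_x[, 1]), ylim = range(all_x[, 2]),
    pch = 19, col = "darkgreen", xlab = colnames(sc$species_points)[1],
    ylab = colnames(sc$species_points)[2], ...
  )
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::arrows(0, 0, sc$response_arrows[, 1], sc$response_arrows[, 2],
    length = 0.08, col = "blue"
  )
  graphics::text(sc$response_arrows * 1.08, labels = rownames(sc$response_arrows), col = "blue", cex = 0.8)
  if (!is.null(sc$constraint_arrows)) {
    graphics::arrows(0, 0, sc$constraint_arrows[, 1], sc$constraint_arrows[, 2],
      length = 0.08, col = "red", lty = 2
    )
    graphics::text(sc$constraint_arrows * 1.08,
      labels = rownames(sc$constraint_arrows),
      col = "red", cex = 0.8
    )
  }
  invisible(x)
}
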