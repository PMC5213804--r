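# Independent oracles for the ordination core, deliberately naive:
# per-column least squares through lm(), never through the package's
# projection code.

# explained fraction of total sum of squares, column by column
frac_oracle <- function(Y, X) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Xc <- scale(as.matrix(X), scale = FALSE)
  ss_fit <- 0
  for (j in seq_len(ncol(Yc))) {
    fit <- lm(Yc[, j] ~ Xc)
    ss_fit <- ss_fit + sum(fitted(fit)^2)
  }
  ss_fit / sum(Yc^2)
}

# pseudo-F from per-column sums of squares and the qr rank of X
pseudo_f_oracle <- function(Y, X) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Xc <- scale(as.matrix(X), scale = FALSE)
  q <- qr(Xc)$rank
  n <- nrow(Yc)
  ss_fit <- 0
  for (j in seq_len(ncol(Yc))) {
    ss_fit <- ss_fit + sum(fitted(lm(Yc[, j] ~ Xc))^2)
  }
  ss_res <- sum(Yc^2) - ss_fit
  (ss_fit / q) / (ss_res / (n - 1 - q))
}

# random centred test matrices with row names
rand_mat <- function(n, p, prefix = "v") {
  m <- matrix(rnorm(n * p), n, p,
    dimnames = list(paste0("s", seq_len(n)), paste0(prefix, seq_len(p)))
  )
  m
}

fixture_cov <- function() {
  fx <- snake_fixture()
  list(
    fx = fx,
    Y = response_matrix(fx$traits, scaling = "covariance"),
    E = ecology_matrix(fx$traits)
  )
}

# clade matrix of the fixture tree aligned to the trait-table row order
fixture_clades <- function(fx, ...) {
  cm <- clade_indicators(fx$tree, ...)
  idx <- match(gsub(" ", "_", fx$traits$species_id), rownames(cm))
  out <- cm[idx, , drop = FALSE]
  rownames(out) <- fx$traits$species_id
  out
}
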