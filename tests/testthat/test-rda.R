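test_that("explained fractions match the per-column least-squares oracle", {
  set.seed(11)
  for (rep in 1:10) {
    Y <- rand_mat(12, 4)
    X <- rand_mat(12, 3, "x")
    fit <- rda_fit(Y, X)
    expect_equal(fit$fraction, frac_oracle(Y, X), tolerance = 1e-10)
    expect_equal(pseudo_f(fit), pseudo_f_oracle(Y, X), tolerance = 1e-10)
    # eigenvalues decompose the constrained inertia, non-increasing
    expect_equal(sum(fit$eig), fit$constrained_chi, tolerance = 1e-10)
    expect_true(all(diff(fit$eig) <= 1e-12))
  }
})

test_that("degenerate and closed-form cases behave as linear algebra dictates", {
  set.seed(5)
  Y <- rand_mat(10, 3)
  # self-explanation: projection onto its own span
  expect_equal(rda_fit(Y, Y)$fraction, 1, tolerance = 1e-12)
  # single response, single constraint: squared Pearson correlation
  y <- rand_mat(15, 1)
  x <- rand_mat(15, 1, "x")
  expect_equal(rda_fit(y, x)$fraction, cor(y, x)[1]^2, tolerance = 1e-12)
  # orthogonal constraint explains nothing
  y2 <- matrix(c(1, -1, 1, -1, 1, -1), 6, 1, dimnames = list(paste0("s", 1:6), "y"))
  x2 <- matrix(c(1, 1, 1, 1, -1, -1), 6, 1, dimnames = list(paste0("s", 1:6), "x"))
  f0 <- rda_fit(y2, x2)
  expect_equal(f0$fraction, 0, tolerance = 1e-12)
  expect_equal(pseudo_f(f0), 0, tolerance = 1e-12)
  # monotonicity: adding a column never decreases explained inertia
  set.seed(6)
  Y <- rand_mat(14, 3)
  X <- rand_mat(14, 4, "x")
  fr <- vapply(
    seq_len(4),
    function(k) rda_fit(Y, X[, seq_len(k), drop = FALSE])$constrained_chi,
    numeric(1)
  )
  expect_true(all(diff(fr) >= -1e-12))
})

test_that("rank-deficient dummy blocks are projected via their true rank", {
  fx <- snake_fixture()
  Y <- response_matrix(fx$traits, scaling = "covariance")
  E <- ecology_matrix(fx$traits) # two redundant blocks of 4 dummies
  fit <- rda_fit(Y, E)
  # independent rank oracle: 8 dummy columns collapse after centring
  # (each block loses one dimension, and the two blocks share another)
  q_true <- qr(scale(unclass(E), scale = FALSE))$rank
  expect_lt(q_true, ncol(E))
  expect_equal(fit$q, q_true)
  expect_equal(fit$fraction, frac_oracle(Y, E), tolerance = 1e-10)
  expect_equal(fit$df_residual, 17L - 1L - q_true)
})

test_that("partial fits residualise on the condition and report against original inertia", {
  set.seed(21)
  Y <- rand_mat(12, 4)
  X <- rand_mat(12, 2, "x")
  W <- rand_mat(12, 2, "w")
  fit <- rda_fit(Y, X, condition = W)
  # conditioning on X itself leaves nothing to explain
  expect_lt(rda_fit(Y, X, condition = X)$constrained_chi, 1e-20)
  # additivity: condition chi + constrained chi = joint fit of [W X]
  joint <- rda_fit(Y, cbind(W, X))
  expect_equal(fit$cond_chi + fit$constrained_chi, joint$constrained_chi,
    tolerance = 1e-10
  )
  # partial fraction uses the ORIGINAL total inertia as denominator
  expect_equal(fit$fraction, fit$constrained_chi / joint$tot_chi, tolerance = 1e-12)
  expect_equal(fit$df_residual, 12L - 1L - 2L - 2L)
})

test_that("results agree with an independent constrained-ordination implementation", {
  skip_if_not_installed("vegan")
  set.seed(31)
  Y <- rand_mat(15, 5)
  X <- rand_mat(15, 3, "x")
  W <- rand_mat(15, 1, "w")
  ours <- rda_fit(Y, X)
  ref <- vegan::rda(Y ~ x1 + x2 + x3, data = as.data.frame(X))
  expect_equal(ours$tot_chi, ref$tot.chi, tolerance = 1e-10)
  expect_equal(ours$constrained_chi, ref$CCA$tot.chi, tolerance = 1e-10)
  expect_equal(unname(ours$eig), unname(ref$CCA$eig), tolerance = 1e-8)

  oursw <- rda_fit(Y, X, condition = W)
  d <- data.frame(X, W)
  refw <- vegan::rda(Y ~ x1 + x2 + x3 + Condition(w1), data = d)
  expect_equal(oursw$constrained_chi, refw$CCA$tot.chi, tolerance = 1e-10)
  expect_equal(oursw$cond_chi, refw$pCCA$tot.chi, tolerance = 1e-10)
})

test_that("input validation catches misalignment and empty variance", {
  Y <- rand_mat(8, 2)
  X <- rand_mat(8, 1, "x")
  Xbad <- X
  rownames(Xbad) <- rev(rownames(X))
  expect_error(rda_fit(Y, Xbad), "not aligned")
  expect_error(rda_fit(Y[1:2, ], X[1:2, , drop = FALSE]), "at least 3")
  Yconst <- matrix(1, 8, 2, dimnames = dimnames(Y))
  expect_error(rda_fit(Yconst, X), "zero total inertia")
})

test_that("permutation tests are reproducible and correctly calibrated at the edge", {
  set.seed(41)
  Y <- rand_mat(10, 3)
  X <- rand_mat(10, 2, "x")
  a <- rda_permtest(Y, X, permutations = 199, seed = 99)
  b <- rda_permtest(Y, X, permutations = 199, seed = 99)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$p_value, (a$n_as_extreme + 1) / 200)
  expect_gte(a$p_value, 1 / 200)
  expect_lte(a$p_value, 1)

  # a perfect predictor with all rows distinct attains the floor
  y <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 8, 1, dimnames = list(paste0("s", 1:8), "y"))
  pt <- rda_permtest(y, y * 2 + 1, permutations = 99, seed = 7)
  expect_equal(pt$p_value, 1 / 100)
})

test_that("axis shares use the requested denominator", {
  set.seed(51)
  Y <- rand_mat(12, 4)
  X <- rand_mat(12, 3, "x")
  fit <- rda_fit(Y, X)
  k <- length(fit$eig)
  expect_equal(axis_fraction(fit, k), 1)
  expect_equal(axis_fraction(fit, k + 5), 1) # clamps
  expect_equal(
    axis_fraction(fit, 2, denominator = "total"),
    sum(fit$eig[1:2]) / fit$tot_chi
  )
  # a rank-1 constraint yields a single canonical axis
  f1 <- rda_fit(Y, X[, 1, drop = FALSE])
  expect_equal(axis_fraction(f1, 1), 1)
  expect_equal(length(f1$eig), 1L)
})

test_that("model methods are mutually consistent", {
  set.seed(61)
  Y <- rand_mat(12, 3)
  X <- rand_mat(12, 2, "x")
  fit <- rda_fit(Y, X)
  expect_equal(fitted(fit) + residuals(fit), fit$Y, tolerance = 1e-12)
  # coefficients reproduce the fitted values
  expect_equal(fit$X %*% coef(fit), fitted(fit), tolerance = 1e-10)
  # predict on the training rows (uncentred) equals fitted
  expect_equal(
    unname(predict(fit, sweep(X, 2, colMeans(X) * 0, "-"))),
    unname(fitted(fit)),
    tolerance = 1e-10
  )
})

test_that("triplot scores encode correlation geometry", {
  fx <- snake_fixture()
  res <- cpo_analysis(fx$traits, fx$tree, permutations = 199, seed = 42)
  tp <- res$triplot
  # complementary mode dummies: exactly antiparallel arrows
  expect_equal(tp$response_arrows["oviparous", ],
    -tp$response_arrows["viviparous", ],
    tolerance = 1e-10
  )
  cosang <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  # aquatic species are the viviparous ones: sharp positive angle
  expect_gt(cosang(
    tp$constraint_arrows["aquatic", ],
    tp$response_arrows["viviparous", ]
  ), 0.5)
  # terrestrial/fossorial Xenodon: obtuse angle with aquatic
  expect_lt(cosang(
    tp$constraint_arrows["aquatic", ],
    tp$constraint_arrows["Xenodon", ]
  ), 0)
})
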