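test_that("marginal clade tests rank clades by their lone explained fraction", {
  fc <- fixture_cov()
  cm <- fixture_clades(fc$fx, min_size = 1, labelled_only = TRUE)
  tab <- clade_tests(fc$Y, cm, permutations = 199, seed = 3)
  expect_s3_class(tab, "clade_test_table")
  expect_equal(tab$clade[1], "Hydrodynastini")
  expect_true(all(diff(tab$fraction) <= 1e-12))
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))
  # marginal fraction of each clade equals its lone-fit oracle value
  for (i in seq_len(3)) {
    expect_equal(
      tab$fraction[i],
      frac_oracle(fc$Y, cm[, tab$clade[i], drop = FALSE]),
      tolerance = 1e-10
    )
  }
  expect_error(clade_tests(fc$Y, cm[, 0]), "empty clade set")
})

test_that("forward selection adds the largest admissible gain and stops honestly", {
  set.seed(8)
  # a candidate that generates a response column is picked immediately
  Y <- rand_mat(14, 2)
  gen <- Y[, 1, drop = FALSE] + matrix(rnorm(14, 0, 1e-3), 14, 1)
  colnames(gen) <- "gen"
  noise <- rand_mat(14, 1, "noise")
  cand <- cbind(gen, noise)
  sel <- forward_select(Y, cand, permutations = 199, seed = 5)
  expect_equal(attr(sel, "selected")[1], "gen")

  # single pure-noise candidate: empty selection in about 95% of runs
  empties <- 0L
  for (s in 1:120) {
    set.seed(s)
    Yn <- rand_mat(12, 2)
    Xn <- rand_mat(12, 1, "x")
    fs <- forward_select(Yn, Xn, alpha = 0.05, permutations = 99, seed = s)
    if (length(attr(fs, "selected")) == 0L) empties <- empties + 1L
  }
  expect_gt(empties / 120, 0.85)

  # candidate column order does not change the selection (fixed seed policy)
  fc <- fixture_cov()
  cm <- fixture_clades(fc$fx, min_size = 1, labelled_only = TRUE)
  s1 <- forward_select(fc$Y, cm, alpha = 0.10, permutations = 499, seed = 11)
  s2 <- forward_select(fc$Y, cm[, rev(colnames(cm))], alpha = 0.10, permutations = 499, seed = 11)
  expect_equal(attr(s1, "selected"), attr(s2, "selected"))
})

test_that("the fixture selection matches the study's three clades and one ecological variable", {
  fx <- snake_fixture()
  res <- cpo_analysis(fx$traits, fx$tree, permutations = 999, seed = 42)
  expect_equal(attr(res$ecology$selection, "selected"), "aquatic")
  expect_equal(
    attr(res$cpo$selection, "selected"),
    c("Hydrodynastini", "Hydropsini", "Xenodon")
  )
  # sequential contributions reproduce the published contribution table
  steps <- as.data.frame(res$cpo$selection)
  expect_equal(steps$added_fraction, c(0.423, 0.205, 0.094), tolerance = 0.01)
  # the single-species top clade sits at the permutation resolution floor
  # (1/17 in expectation), so the strict 0.05 threshold admits nothing
  # once enough permutations pin the p-value down
  strict <- cpo_analysis(fx$traits, fx$tree,
    clade_alpha = 0.05,
    permutations = 9999, seed = 42
  )
  expect_equal(length(attr(strict$cpo$selection, "selected")), 0L)
  expect_null(strict$partition)
  stopped <- attr(strict$cpo$selection, "stopped_at")
  expect_equal(stopped$variable, "Hydrodynastini")
  expect_equal(stopped$p, 1 / 17, tolerance = 0.15)
})

test_that("variance partition identities hold exactly", {
  fc <- fixture_cov()
  cm <- fixture_clades(fc$fx, min_size = 1, labelled_only = TRUE)
  Xp <- cm[, c("Hydrodynastini", "Hydropsini", "Xenodon")]
  Xe <- unclass(fc$E)[, "aquatic", drop = FALSE]
  vp <- variance_partition(fc$Y, Xp, Xe)
  expect_equal(vp$A + vp$C, vp$R_phy, tolerance = 1e-10)
  expect_equal(vp$B + vp$C, vp$R_eco, tolerance = 1e-10)
  expect_equal(vp$A + vp$B + vp$C, vp$R_joint, tolerance = 1e-10)
  expect_equal(vp$A + vp$B + vp$C + vp$U, 1, tolerance = 1e-10)
  # unique fractions re-derived by partial RDA agree exactly
  expect_equal(vp$A, rda_fit(fc$Y, Xp, condition = Xe)$fraction, tolerance = 1e-10)
  expect_equal(vp$B, rda_fit(fc$Y, Xe, condition = Xp)$fraction, tolerance = 1e-10)
  # identical explanatory sets: no unique components
  vpx <- variance_partition(fc$Y, Xe, Xe)
  expect_equal(vpx$A, 0, tolerance = 1e-12)
  expect_equal(vpx$B, 0, tolerance = 1e-12)
  expect_equal(vpx$C, vpx$R_eco, tolerance = 1e-12)

  # and on random data too
  set.seed(9)
  for (i in 1:5) {
    Y <- rand_mat(13, 3)
    A <- rand_mat(13, 2, "a")
    B <- rand_mat(13, 2, "b")
    v <- variance_partition(Y, A, B)
    expect_equal(v$A + v$B + v$C + v$U, 1, tolerance = 1e-10)
    expect_equal(v$A, rda_fit(Y, A, condition = B)$fraction, tolerance = 1e-10)
  }
})

test_that("the full pipeline degrades gracefully without ecological variables", {
  fx <- snake_fixture()
  res <- cpo_analysis(fx$traits, fx$tree,
    eco_vars = character(0),
    permutations = 999, seed = 1
  )
  expect_null(res$ecology$selection)
  expect_null(res$partition)
  expect_s3_class(res$cpo$marginal, "clade_test_table")
  expect_gt(length(attr(res$cpo$selection, "selected")), 0L)
})

test_that("stage errors carry the stage name", {
  fx <- snake_fixture()
  broken <- fx$traits
  broken$mf[1] <- NA
  expect_error(cpo_analysis(broken, fx$tree, permutations = 19, seed = 1), "coding stage")
  drop_tip_tree <- ape::drop.tip(fx$tree, "Xenodon_merremii")
  expect_error(
    cpo_analysis(fx$traits, drop_tip_tree, permutations = 19, seed = 1),
    "missing from tree"
  )
})

test_that("reports round-trip through JSON and carry the selected variables", {
  fx <- snake_fixture()
  res <- cpo_analysis(fx$traits, fx$tree, permutations = 199, seed = 7)
  path <- file.path(tempdir(), "report.json")
  write_report(res, path)
  back <- read_report(path)
  expect_equal(back$schema_version, "1.0")
  expect_equal(back$config$permutations, 199)
  expect_equal(unlist(back$ecology$selection$selected), "aquatic")
  expect_equal(
    unlist(back$cpo$selection$selected),
    c("Hydrodynastini", "Hydropsini", "Xenodon")
  )
  expect_equal(back$partition$A, res$partition$A, tolerance = 1e-12)
  expect_equal(
    back$cpo$marginal$fraction,
    res$cpo$marginal$fraction,
    tolerance = 1e-12
  )
  expect_error(
    write_report(res, file.path(tempdir(), "no_such_dir_xyz", "r.json")),
    "directory"
  )
})
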