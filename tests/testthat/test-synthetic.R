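test_that("simulated Yule trees have the right shape", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(all(t2$edge.length > 0))

  t131 <- simulate_tree(131, seed = 2)
  expect_equal(ape::Ntip(t131), 131)
  expect_equal(t131$Nnode, 130)  # fully bifurcating: n - 1 internal splits
  expect_identical(simulate_tree(131, seed = 2)$edge.length, t131$edge.length)
})

test_that("predictor simulation hits declared frequencies and missingness", {
  full <- simulate_predictors(131, missing_rate = 0, seed = 3)
  expect_false(anyNA(full$socio[socio_predictors()]))

  pm <- simulate_predictors(131, missing_rate = 24 / 786, seed = 4)
  n_miss <- sum(is.na(pm$socio[socio_predictors()]))
  # Binomial(786, 24/786): mean 24, sd ~4.8
  expect_gt(n_miss, 5)
  expect_lt(n_miss, 45)
  expect_identical(pm$complete[!pm$mask[, "external_trade"], "external_trade"],
                   pm$socio[!pm$mask[, "external_trade"], "external_trade"])

  big <- simulate_predictors(5000, missing_rate = 0, seed = 5)
  # binary frequencies within 3 SE of their generating probabilities
  p_trade <- mean(big$socio$external_trade)
  expect_lt(abs(p_trade - 0.55), 3 * sqrt(0.55 * 0.45 / 5000))
  p_strat <- mean(big$socio$social_stratification)
  expect_lt(abs(p_strat - 0.45), 3 * sqrt(0.45 * 0.55 / 5000))
})

test_that("outcome simulation respects the inverse link at null parameters", {
  n <- 600
  tree <- simulate_tree(n, seed = 6)
  socio <- simulate_predictors(n, missing_rate = 0, seed = 7,
                               society_id = tree$tip.label)$socio
  docs <- data.frame(society_id = tree$tip.label,
                     page_count = rep(c(100L, 200L), n / 2),
                     pub_year = 1950L, female_coauthor = 0L)
  truth <- punish_truth("null", signal = 1e-6, tau = 1e-6)
  truth$beta[] <- 0
  spec <- model_spec(outcomes = truth$outcomes, predictors = truth$predictors)
  X <- build_design(socio, docs, spec, taxa_order = tree$tip.label)

  truth$alpha[] <- 0
  Y0 <- simulate_outcomes(tree, X, truth, seed = 8)
  expect_true(all(abs(colMeans(Y0) - 0.5) < 3 * sqrt(0.25 / n)))

  truth$alpha[] <- qlogis(0.3)
  Y3 <- simulate_outcomes(tree, X, truth, seed = 9)
  expect_true(all(abs(colMeans(Y3) - 0.3) < 3 * sqrt(0.3 * 0.7 / n) + 0.01))
})

test_that("strong phylogenetic signal clusters outcomes on the tree", {
  n <- 200
  tree <- simulate_tree(n, seed = 10)
  C <- unclass(phylo_corr(tree))
  truth <- punish_truth("null", K = 1, signal = 0.7, tau = 0.3,
                        predictors = "external_trade")
  truth$beta[] <- 0
  X <- matrix(rbinom(n, 1, 0.5), n, 1,
              dimnames = list(tree$tip.label, "external_trade"))
  Y <- simulate_outcomes(tree, X, truth, seed = 11)
  # agreement between outcome products and phylogenetic proximity
  sgn <- 2 * Y[, 1] - 1
  prod_mat <- tcrossprod(sgn)
  off <- upper.tri(C)
  r <- cor(C[off], prod_mat[off])
  expect_gt(r, 0.05)

  # and the generator's own truth scores better than a perturbed alternative
  ll_true <- log_likelihood(list(alpha = truth$alpha, beta = truth$beta,
                                 phi = attr(Y, "phi"), u = attr(Y, "u")), X, Y)
  ll_pert <- log_likelihood(list(alpha = truth$alpha + 2, beta = truth$beta,
                                 phi = attr(Y, "phi"), u = attr(Y, "u")), X, Y)
  expect_gt(ll_true, ll_pert)
})

test_that("study fixtures are valid, deterministic, and in the prevalence band", {
  fx <- make_study_fixture(seed = 5)
  expect_s3_class(fx$evidence, "evidence_matrix")  # invariants checked on build
  expect_equal(length(fx$evidence$society_id), 131)
  prev <- colMeans(fx$evidence$punishments)
  expect_true(all(prev >= 0.15 & prev <= 0.5))

  fx2 <- make_study_fixture(seed = 5)
  expect_identical(fx$evidence$cells, fx2$evidence$cells)
  expect_identical(fx$socio, fx2$socio)
  expect_false(identical(fx$evidence$cells,
                         make_study_fixture(seed = 6)$evidence$cells))
})

test_that("fixtures round-trip through the coding-table CSV", {
  fx <- make_study_fixture(seed = 12, n = 40)
  d <- tempfile()
  write_study_fixture(fx, d)
  expect_true(file.exists(file.path(d, "truth.json")))
  back <- suppressMessages(read_coding_table(file.path(d, "coding_table.csv")))
  expect_identical(back$evidence$cells, fx$evidence$cells)
  expect_identical(back$evidence$punishments, fx$evidence$punishments)
  expect_equal(back$socio[socio_predictors()], fx$socio[socio_predictors()])
  tree_back <- parse_newick(readLines(file.path(d, "tree.nwk")))
  expect_setequal(tree_back$tip.label, fx$tree$tip.label)
})
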