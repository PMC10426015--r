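# Small shared instance so the MCMC unit tests stay fast.
small_instance <- function(S = 24, K = 2, seed = 50) {
  tree <- simulate_tree(S, seed = seed)
  C <- phylo_corr(tree)
  truth <- punish_truth("null", K = K, signal = 0.1, tau = 0.5,
                        predictors = c("external_trade", "food_storage"))
  set.seed(seed + 1)
  X <- cbind(external_trade = rbinom(S, 1, 0.5),
             food_storage = rbinom(S, 1, 0.5))
  rownames(X) <- tree$tip.label
  Y <- simulate_outcomes(tree, X, truth, seed = seed + 2)
  spec <- model_spec(outcomes = truth$outcomes,
                     predictors = c("external_trade", "food_storage"))
  list(spec = spec, X = X, Y = Y, C = C)
}

test_that("identical seed and configuration reproduce identical draws", {
  ins <- small_instance()
  f1 <- fit_mcmc(ins$spec, ins$X, ins$Y, ins$C, chains = 2, draws = 60,
                 warmup = 80, seed = 99)
  f2 <- fit_mcmc(ins$spec, ins$X, ins$Y, ins$C, chains = 2, draws = 60,
                 warmup = 80, seed = 99)
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$Omega, f2$draws$Omega)
  f3 <- fit_mcmc(ins$spec, ins$X, ins$Y, ins$C, chains = 2, draws = 60,
                 warmup = 80, seed = 100)
  expect_false(identical(f1$draws$beta, f3$draws$beta))
  expect_error(fit_mcmc(ins$spec, ins$X, ins$Y, ins$C, chains = 1, draws = 60),
               "2 chains")
})

test_that("with zero observation weight the posterior returns the prior", {
  # all-missing likelihood stub: marginal posteriors must match their priors
  ins <- small_instance(S = 12)
  W <- matrix(0, 12, 2)
  fit <- fit_mcmc(ins$spec, ins$X, ins$Y, ins$C, chains = 2, draws = 700,
                  warmup = 400, seed = 31, obs_weights = W)
  b <- as.vector(fit$draws$beta)
  expect_lt(abs(mean(b)), 0.35)         # prior mean 0
  expect_lt(abs(sd(b) - 2.5), 0.45)     # prior SD s_beta = 2.5
  a <- as.vector(fit$draws$alpha)
  expect_lt(abs(sd(a) - 2.5), 0.5)
  # half-normal(0, 1.5) has mean 1.5*sqrt(2/pi) ~ 1.20
  expect_lt(abs(mean(fit$draws$sigma_phylo) - 1.5 * sqrt(2 / pi)), 0.3)
})

test_that("fits expose diagnostics and flag thresholds", {
  ins <- small_instance()
  fit <- fit_mcmc(ins$spec, ins$X, ins$Y, ins$C, chains = 2, draws = 80,
                  warmup = 100, seed = 1)
  d <- fit$diagnostics
  expect_true(all(is.finite(d$rhat) | is.na(d$rhat)))
  expect_equal(length(d$rhat), fit$n_params)
  expect_true(length(d$ess) >= 2 + 4 + 4 + 1)
  expect_true(d$divergence_rate >= 0)
  # a deliberately tiny run cannot reach ESS 400 and must say so
  expect_true(any(grepl("ESS", d$flags)))
  expect_output(print(fit), "punish_fit")
})

test_that("the univariate-response variant (K = 1) fits cleanly", {
  ins <- small_instance(K = 1, seed = 61)
  spec1 <- model_spec(outcomes = ins$spec$outcomes[1],
                      predictors = ins$spec$predictors)
  fit <- fit_mcmc(spec1, ins$X, ins$Y[, 1, drop = FALSE], ins$C,
                  chains = 2, draws = 100, warmup = 120, seed = 3)
  expect_equal(dim(fit$draws$beta)[2], 1)
  expect_equal(dim(fit$draws$Omega)[2:3], c(1, 1))
  expect_true(all(fit$draws$Omega == 1))
  sig <- phylogenetic_signal(fit)
  expect_true(all(sig >= 0 & sig <= 1))
})

test_that("phylogenetic signal follows its variance-partition formula", {
  fake <- structure(list(
    outcome_names = c("a", "b"),
    draws = list(
      sigma_phylo = cbind(a = rep(pi / sqrt(3), 10), b = rep(0, 10)),
      tau = cbind(a = rep(0, 10), b = rep(2, 10))
    )
  ), class = "punish_fit")
  sig <- phylogenetic_signal(fake)
  expect_equal(unname(sig[1, "a"]), 0.5)  # sigma^2 = pi^2/3, tau = 0
  expect_equal(unname(sig[1, "b"]), 0)    # sigma = 0
})

test_that("the bias model fits document covariates and rejects degenerate ones", {
  S <- 40
  tree <- simulate_tree(S, seed = 70)
  C <- phylo_corr(tree)
  set.seed(71)
  docs <- data.frame(
    society_id = tree$tip.label,
    page_count = pmax(1L, as.integer(rlnorm(S, log(120), 0.7))),
    pub_year = sample(1900:1990, S, replace = TRUE),
    female_coauthor = rbinom(S, 1, 0.2)
  )
  eta <- 1.2 * scale(log(docs$page_count))[, 1]
  Y <- cbind(material = rbinom(S, 1, plogis(eta)))
  rownames(Y) <- tree$tip.label
  spec <- model_spec(outcomes = "material",
                     predictors = c("log_pages", "pub_year", "female_coauthor"))
  fit <- fit_bias_model(docs, Y, C, chains = 2, draws = 150, warmup = 150,
                        seed = 5, spec = spec)
  expect_equal(fit$predictor_names,
               c("log_pages", "pub_year", "female_coauthor"))

  docs_bad <- docs
  docs_bad$female_coauthor <- 0L
  expect_error(
    fit_bias_model(docs_bad, Y, C, chains = 2, draws = 50, warmup = 50,
                   seed = 5, spec = spec),
    "female_coauthor"
  )
})

test_that("mixture pooling over identical tables matches a plain fit in distribution", {
  ins <- small_instance(S = 20, seed = 81)
  socio <- simulate_predictors(20, missing_rate = 0, seed = 82,
                               society_id = rownames(ins$C))$socio
  spec <- model_spec(outcomes = ins$spec$outcomes,
                     predictors = c("external_trade", "food_storage"))
  imp <- impute_chained(socio, m = 2, seed = 1)  # complete -> identical copies
  plan <- pool_for_fitting(imp, "mixture")
  docs <- NULL
  X <- build_design(socio, docs, spec, taxa_order = rownames(ins$C))
  f_plain <- fit_mcmc(spec, X, ins$Y, ins$C, chains = 2, draws = 500,
                      warmup = 300, seed = 7)
  f_mix <- fit_pooled(spec, plan, docs, ins$Y, ins$C, chains = 2, draws = 500,
                      warmup = 300, seed = 8)
  # identical tables: the mixture likelihood is exactly the single-table one.
  # thinned before the KS test so the draws are close to independent
  thin <- seq(1, 1000, by = 5)
  ks <- suppressWarnings(stats::ks.test(f_plain$draws$beta[thin, 1, 1],
                                        f_mix$draws$beta[thin, 1, 1]))
  expect_gt(ks$p.value, 0.01)
})
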