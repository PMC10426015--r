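test_that("log-likelihood equals hand values in degenerate cases", {
  X <- matrix(0.7, 1, 1)
  Y <- matrix(1, 1, 1)
  p0 <- list(alpha = 0, beta = matrix(0, 1, 1),
             phi = matrix(0, 1, 1), u = matrix(0, 1, 1))
  expect_equal(log_likelihood(p0, X, Y), log(0.5))

  # saturation: huge intercept with y = 1 -> log-likelihood -> 0
  psat <- p0; psat$alpha <- 50
  expect_equal(log_likelihood(psat, X, Y), 0, tolerance = 1e-12)
  # contrary observation at saturation -> -Inf, no exception
  pinf <- p0; pinf$alpha <- Inf
  expect_identical(log_likelihood(pinf, X, matrix(0, 1, 1)), -Inf)
})

test_that("log-likelihood matches the straight-loop oracle on small instances", {
  set.seed(17)
  for (r in 1:5) {
    S <- 6; K <- 2; P <- 3
    X <- matrix(rnorm(S * P), S, P)
    Y <- matrix(rbinom(S * K, 1, 0.5), S, K)
    pp <- random_params(S, K, P)
    expect_equal(log_likelihood(pp, X, Y),
                 oracle_loglik(pp$alpha, pp$beta, pp$phi, pp$u, X, Y),
                 tolerance = 1e-10)
  }
})

test_that("log-prior closed forms: zero point, scale doubling, identity C", {
  S <- 4; K <- 2; P <- 2
  spec1 <- model_spec(outcomes = c("a", "b"),
                      predictors = c("external_trade", "food_storage"),
                      s_alpha = 1, s_beta = 1, s_sd = 1, lkj_eta = 1)
  pz <- list(alpha = rep(0, K), beta = matrix(0, K, P),
             sigma_phylo = rep(1, K), tau = rep(1, K), Omega = diag(K),
             phi = matrix(0, S, K), u = matrix(0, S, K))
  C <- diag(S)
  # with everything at 0/1 and unit scales the value is a sum of constants:
  # K normals (alpha) + K*P normals (beta) + 2K half-normals at 1 +
  # K * S-dim MVN at 0 + S * K-dim MVN at 0
  expected <- (K + K * P) * (-0.5 * log(2 * pi)) +
    2 * K * (log(2) - 0.5 * log(2 * pi) - 0.5) +
    K * (-0.5 * S * log(2 * pi)) + S * (-0.5 * K * log(2 * pi))
  expect_equal(log_prior(pz, C, spec1), expected, tolerance = 1e-12)

  # doubling s_beta lowers the density at beta = 0 by K*P*log(2)
  spec2 <- model_spec(outcomes = c("a", "b"),
                      predictors = c("external_trade", "food_storage"),
                      s_alpha = 1, s_beta = 2, s_sd = 1, lkj_eta = 1)
  expect_equal(log_prior(pz, C, spec2) - log_prior(pz, C, spec1),
               -K * P * log(2), tolerance = 1e-12)

  # with C = identity the phi term is a product of independent normals
  set.seed(2)
  pp <- pz; pp$phi <- matrix(rnorm(S * K), S, K)
  indep <- sum(dnorm(pp$phi, 0, 1, log = TRUE)) - sum(dnorm(0 * pp$phi, 0, 1, log = TRUE))
  expect_equal(log_prior(pp, C, spec1) - log_prior(pz, C, spec1), indep,
               tolerance = 1e-12)

  # non-PD Omega -> -Inf
  pbad <- pz; pbad$Omega <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_identical(log_prior(pbad, C, spec1), -Inf)
})

test_that("log-prior matches the straight-loop oracle on random parameters", {
  set.seed(23)
  tree <- simulate_tree(5, seed = 3)
  C <- unclass(phylo_corr(tree))
  spec <- model_spec(outcomes = c("a", "b"),
                     predictors = c("external_trade", "food_storage", "log_pages"))
  for (r in 1:5) {
    pp <- random_params(5, 2, 3)
    expect_equal(log_prior(pp, C, spec),
                 oracle_logprior(pp, C, spec$s_alpha, spec$s_beta, spec$s_sd,
                                 spec$lkj_eta),
                 tolerance = 1e-8)
  }
})

test_that("the compiled objective agrees with the R transform + likelihood + prior", {
  # evaluates the non-centred posterior two ways: the compiled autodiff
  # objective, and centre_params -> log_likelihood + log_prior plus the
  # transform terms (z densities swapped for centred MVN densities via the
  # triangular-map Jacobian)
  set.seed(41)
  S <- 6; K <- 3; P <- 2
  tree <- simulate_tree(S, seed = 6)
  C <- unclass(phylo_corr(tree))
  LC <- t(chol(C))
  spec <- model_spec(outcomes = paste0("o", 1:K),
                     predictors = c("external_trade", "log_pages"))
  X <- matrix(rnorm(S * P), S, P)
  Y <- matrix(rbinom(S * K, 1, 0.5), S, K)
  storage.mode(Y) <- "double"
  obj <- TMB::MakeADFun(
    data = list(Y = Y, X = array(X, c(S, P, 1)),
                B = Matrix::Matrix(LC, sparse = TRUE),
                W = matrix(1, S, K), s_alpha = spec$s_alpha,
                s_beta = spec$s_beta, s_sd = spec$s_sd,
                lkj_eta = spec$lkj_eta, use_u = 1L),
    parameters = punishr:::param_skeleton(S, K, P), DLL = "punishr",
    silent = TRUE
  )
  for (r in 1:5) {
    theta <- rnorm(length(obj$par), 0, 0.7)
    nc <- punishr:::split_theta(theta, S, K, P)
    cp <- punishr:::centre_params(nc, LC)
    # change of variables: from centred MVN densities back to z densities
    sig <- cp$sigma_phylo; tau <- cp$tau
    jac <- sum(log(2) + dnorm(sig, 0, spec$s_sd, log = TRUE) + log(sig)) +
      sum(log(2) + dnorm(tau, 0, spec$s_sd, log = TRUE) + log(tau)) +
      sum(dnorm(nc$z_phi, log = TRUE)) + sum(dnorm(nc$z_u, log = TRUE)) +
      lkj_terms(nc$omega_raw, K, spec$lkj_eta)
    manual <- log_likelihood(cp, X, Y) +
      sum(dnorm(cp$alpha, 0, spec$s_alpha, log = TRUE)) +
      sum(dnorm(cp$beta, 0, spec$s_beta, log = TRUE)) + jac
    expect_equal(-as.numeric(obj$fn(theta)), manual, tolerance = 1e-8)
  }

  # gradient against central finite differences
  theta <- rnorm(length(obj$par), 0, 0.4)
  g <- -as.vector(obj$gr(theta))
  h <- 1e-6
  idx <- sample(length(theta), 15)
  for (j in idx) {
    e <- rep(0, length(theta)); e[j] <- h
    gn <- (-as.numeric(obj$fn(theta + e)) + as.numeric(obj$fn(theta - e))) / (2 * h)
    expect_equal(g[j], gn, tolerance = 1e-4)
  }
})
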