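#' Bernoulli-logit log-likelihood of the multi-response model
#'
#' Sums, over societies and outcomes, the Bernoulli log-mass with success
#' probability `plogis(alpha_k + x_s' beta_k + phi[s,k] + u[s,k])`. The
#' computation is carried out on the logit scale, so a saturated probability
#' with a contrary observation yields `-Inf` rather than an error.
#'
#' @param params list with `alpha` (K), `beta` (K x P), `phi` (S x K),
#'   `u` (S x K); `phi`/`u` may be omitted (treated as zero).
#' @param design S x P design matrix.
#' @param outcomes S x K binary outcome matrix.
#' @return scalar log-probability.
#' @export
log_likelihood <- function(params, design, outcomes) {
  Y <- as.matrix(outcomes)
  X <- as.matrix(design)
  S <- nrow(Y); K <- ncol(Y)
  stopifnot(nrow(X) == S, length(params$alpha) == K)
  beta <- matrix(params$beta, nrow = K)
  stopifnot(ncol(beta) == ncol(X))
  eta <- matrix(rep(params$alpha, each = S), S, K) + X %*% t(beta)
  if (!is.null(params$phi)) eta <- eta + params$phi
  if (!is.null(params$u)) eta <- eta + params$u
  # log Bernoulli(y | plogis(eta)) = -log1p(exp(-(2y-1) eta)), stably
  q <- -(2 * Y - 1) * eta
  ll <- ifelse(q > 35, -q, -log1p(exp(q)))
  sum(ll)
}

#' Joint log-prior of the multi-response model
#'
#' Evaluates, in the centred parameterisation: normal priors on intercepts and
#' slopes; half-normal priors on the phylogenetic and society-effect SDs;
#' an LKJ(`lkj_eta`) density on the society-effect correlation `Omega`
#' (up to its normalising constant); a multivariate normal
#' `N(0, sigma_phylo_k^2 C)` on each phylogenetic effect column; and a
#' multivariate normal over each society's row of `u` with covariance
#' `diag(tau) Omega diag(tau)`. Returns `-Inf` for a non-positive-definite
#' `Omega` or negative SDs.
#'
#' @param params list with `alpha`, `beta`, `sigma_phylo` (K), `tau` (K),
#'   `Omega` (K x K), `phi` (S x K), `u` (S x K).
#' @param C phylogenetic correlation matrix (S x S).
#' @param spec a [model_spec()] (prior scales).
#' @return scalar log-density.
#' @export
log_prior <- function(params, C, spec) {
  stopifnot(inherits(spec, "model_spec"))
  K <- length(params$alpha)
  if (any(params$sigma_phylo < 0) || any(params$tau < 0)) return(-Inf)
  lp <- sum(stats::dnorm(params$alpha, 0, spec$s_alpha, log = TRUE)) +
    sum(stats::dnorm(params$beta, 0, spec$s_beta, log = TRUE)) +
    sum(stats::dnorm(params$sigma_phylo, 0, spec$s_sd, log = TRUE) + log(2)) +
    sum(stats::dnorm(params$tau, 0, spec$s_sd, log = TRUE) + log(2))

  Omega <- params$Omega
  LOm <- tryCatch(t(chol(Omega)), error = function(e) NULL)
  if (is.null(LOm)) return(-Inf)
  lp <- lp + (spec$lkj_eta - 1) * 2 * sum(log(diag(LOm)))  # (eta-1) log det

  LC <- t(chol(C))
  S <- nrow(C)
  logdetC <- 2 * sum(log(diag(LC)))
  for (k in seq_len(K)) {
    sk <- params$sigma_phylo[k]
    phik <- params$phi[, k]
    if (sk == 0) {
      if (any(phik != 0)) return(-Inf)
      next
    }
    z <- forwardsolve(LC, phik)
    lp <- lp - 0.5 * (S * log(2 * pi) + 2 * S * log(sk) + logdetC) -
      0.5 * sum(z^2) / sk^2
  }
  if (!is.null(params$u)) {
    tau <- params$tau
    if (any(tau == 0)) {
      if (any(params$u != 0)) return(-Inf)
    } else {
      Lu <- diag(tau, K) %*% LOm  # Cholesky of diag(tau) Omega diag(tau)
      logdetU <- 2 * sum(log(diag(Lu)))
      Zu <- forwardsolve(Lu, t(params$u))  # K x S
      lp <- lp - 0.5 * S * (K * log(2 * pi) + logdetU) - 0.5 * sum(Zu^2)
    }
  }
  lp
}

# --- non-centred parameter plumbing (shared by the sampler and tests) ------

param_dims <- function(S, K, P, E = S) {
  n_omega <- max(1L, K * (K - 1L) / 2L)
  list(S = S, K = K, P = P, E = E, n_omega = n_omega,
       D = K + K * P + K + K + n_omega + (E + S) * K)
}

param_skeleton <- function(S, K, P, E = S) {
  list(alpha = numeric(K), beta = matrix(0, K, P),
       log_sigma = numeric(K), log_tau = numeric(K),
       omega_raw = numeric(max(1L, K * (K - 1L) / 2L)),
       z_phi = matrix(0, E, K), z_u = matrix(0, S, K))
}

# Split a flat parameter vector (TMB ordering) into named components.
split_theta <- function(theta, S, K, P, E = S) {
  d <- param_dims(S, K, P, E)
  i <- 0L
  take <- function(n) {
    out <- theta[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  out <- list(
    alpha = take(K),
    beta = matrix(take(K * P), K, P),
    log_sigma = take(K),
    log_tau = take(K),
    omega_raw = take(d$n_omega),
    z_phi = matrix(take(E * K), E, K),
    z_u = matrix(take(S * K), S, K)
  )
  stopifnot(i == d$D)
  out
}

# Lower Cholesky of a K x K correlation matrix from the unconstrained
# canonical-partial-correlation vector (tanh transform).
lkj_chol_from_raw <- function(omega_raw, K) {
  L <- diag(1, K)
  if (K == 1) return(L)
  idx <- 0L
  for (i in 2:K) {
    sumsq <- 0
    for (j in 1:(i - 1)) {
      idx <- idx + 1L
      z <- tanh(omega_raw[idx])
      L[i, j] <- z * sqrt(1 - sumsq)
      sumsq <- sumsq + L[i, j]^2
    }
    L[i, i] <- sqrt(1 - sumsq)
  }
  L
}

# Map non-centred parameters to the centred LatentParameters scale.
# B is any S x E factor with C = B B' (sparse root-path or dense Cholesky).
centre_params <- function(nc, B) {
  K <- length(nc$alpha)
  S <- nrow(B)
  sigma <- exp(nc$log_sigma)
  tau <- exp(nc$log_tau)
  LOm <- lkj_chol_from_raw(nc$omega_raw, K)
  phi <- as.matrix(B %*% nc$z_phi) * rep(sigma, each = S)
  u <- (nc$z_u %*% t(LOm)) * rep(tau, each = S)
  list(alpha = nc$alpha, beta = nc$beta, sigma_phylo = sigma, tau = tau,
       Omega = LOm %*% t(LOm), phi = phi, u = u)
}
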