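# Independent brute-force oracles used to check the package's linear-algebra
# and probability code. These deliberately share no code with the package:
# everything is scalar loops over explicit enumerations.

# Shared-branch covariance by enumerating root-to-leaf edge sets.
oracle_vcv <- function(tree) {
  S <- length(tree$tip.label)
  root <- S + 1L
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(child == node)
      edges <- c(edges, e)
      node <- parent[e]
    }
    edges
  }
  paths <- lapply(seq_len(S), path_edges)
  V <- matrix(0, S, S, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      V[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
    }
  }
  V
}

# Patristic distances from the path enumeration above.
oracle_patristic <- function(tree) {
  V <- oracle_vcv(tree)
  D <- outer(diag(V), diag(V), "+") - 2 * V
  dimnames(D) <- dimnames(V)
  D
}

# Straight-loop Bernoulli-logit log-likelihood, term by term.
oracle_loglik <- function(alpha, beta, phi, u, X, Y) {
  total <- 0
  for (s in seq_len(nrow(Y))) {
    for (k in seq_len(ncol(Y))) {
      eta <- alpha[k] + phi[s, k] + u[s, k]
      for (p in seq_len(ncol(X))) eta <- eta + X[s, p] * beta[k, p]
      pr <- 1 / (1 + exp(-eta))
      total <- total + if (Y[s, k] == 1) log(pr) else log(1 - pr)
    }
  }
  total
}

# Straight-loop log-prior: every term written out from its closed form.
oracle_logprior <- function(params, C, s_alpha, s_beta, s_sd, lkj_eta) {
  K <- length(params$alpha)
  S <- nrow(C)
  ldnorm <- function(x, sd) -0.5 * log(2 * pi) - log(sd) - 0.5 * (x / sd)^2
  lp <- 0
  for (k in seq_len(K)) lp <- lp + ldnorm(params$alpha[k], s_alpha)
  for (k in seq_len(K)) {
    for (p in seq_len(ncol(params$beta))) {
      lp <- lp + ldnorm(params$beta[k, p], s_beta)
    }
  }
  for (k in seq_len(K)) {
    lp <- lp + log(2) + ldnorm(params$sigma_phylo[k], s_sd)
    lp <- lp + log(2) + ldnorm(params$tau[k], s_sd)
  }
  lp <- lp + (lkj_eta - 1) * log(det(params$Omega))
  # MVN(0, sigma_k^2 C) per phylogenetic-effect column
  Cinv <- solve(C)
  ldetC <- determinant(C, logarithm = TRUE)$modulus[1]
  for (k in seq_len(K)) {
    sk <- params$sigma_phylo[k]
    quad <- 0
    for (i in seq_len(S)) {
      for (j in seq_len(S)) {
        quad <- quad + params$phi[i, k] * Cinv[i, j] * params$phi[j, k]
      }
    }
    lp <- lp - 0.5 * (S * log(2 * pi) + 2 * S * log(sk) + ldetC) -
      0.5 * quad / sk^2
  }
  # MVN over u rows with covariance diag(tau) Omega diag(tau)
  Sig <- diag(params$tau, K) %*% params$Omega %*% diag(params$tau, K)
  Siginv <- solve(Sig)
  ldetS <- determinant(Sig, logarithm = TRUE)$modulus[1]
  for (s in seq_len(S)) {
    quad <- 0
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        quad <- quad + params$u[s, i] * Siginv[i, j] * params$u[s, j]
      }
    }
    lp <- lp - 0.5 * (K * log(2 * pi) + ldetS) - 0.5 * quad
  }
  lp
}

# Exhaustive-scan HPDI: every window of ceil(mass*n) sorted samples.
oracle_hpdi <- function(samples, mass) {
  s <- sort(samples)
  n <- length(s)
  w <- ceiling(mass * n)
  best <- c(s[1], s[w])
  for (i in seq_len(n - w + 1)) {
    if (s[i + w - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + w - 1])
  }
  best
}

# Random parameter set on the centred scale for a small instance.
random_params <- function(S, K, P) {
  Omega <- diag(1, K)
  if (K > 1) {
    r <- stats::runif(K * (K - 1) / 2, -0.4, 0.4)
    Omega[lower.tri(Omega)] <- r
    Omega[upper.tri(Omega)] <- t(Omega)[upper.tri(Omega)]
  }
  list(
    alpha = stats::rnorm(K), beta = matrix(stats::rnorm(K * P), K, P),
    sigma_phylo = stats::runif(K, 0.2, 1.5), tau = stats::runif(K, 0.2, 1.5),
    Omega = Omega,
    phi = matrix(stats::rnorm(S * K), S, K),
    u = matrix(stats::rnorm(S * K), S, K)
  )
}

# LKJ density + tanh-transform Jacobian, written out independently.
lkj_terms <- function(omega_raw, K, eta) {
  total <- 0
  idx <- 0
  for (i in 2:K) {
    sumsq <- 0
    for (j in 1:(i - 1)) {
      idx <- idx + 1
      z <- tanh(omega_raw[idx])
      w2 <- 1 - sumsq
      lij <- z * sqrt(w2)
      total <- total + log(1 - z^2) + 0.5 * log(w2)
      sumsq <- sumsq + lij^2
    }
    total <- total + (K - i + 2 * eta - 2) * log(sqrt(1 - sumsq))
  }
  total
}
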