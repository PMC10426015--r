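#' Fit the multi-response phylogenetic logistic regression by HMC
#'
#' Samples the joint posterior of the model by Hamiltonian Monte Carlo on the
#' non-centred parameterisation (standard-normal deviates scaled through the
#' Cholesky factors of the phylogenetic correlation and the society-effect
#' correlation), with dual-averaging step-size adaptation and a diagonal mass
#' matrix estimated during warmup. Gradients come from the compiled
#' autodifferentiated objective.
#'
#' @param spec a [model_spec()].
#' @param design S x P design matrix from [build_design()] (rows in `C`'s
#'   taxa order).
#' @param outcomes S x K binary matrix (or an [evidence_matrix], whose
#'   punishment flags are used), rows in the same order.
#' @param C phylogenetic correlation matrix from [phylo_corr()].
#' @param chains number of chains (>= 2). Default 4.
#' @param draws post-warmup draws per chain. Default 1000.
#' @param warmup warmup iterations per chain. Default `max(300, draws %/% 2)`.
#' @param seed integer seed; fits are reproducible end-to-end.
#' @param obs_weights optional S x K 0/1 matrix; 0 removes an observation from
#'   the likelihood (all-zero weights give prior-only sampling).
#' @param base_steps mean leapfrog steps per proposal. Default 24.
#' @return an object of class `punish_fit`: posterior draws for every model
#'   parameter (intercepts, slopes, SDs, the society-effect correlation, and
#'   the phylogenetic and society effects on the latent scale), per-parameter
#'   split R-hat, effective sample sizes for the structural parameters, and
#'   divergence counts.
#' @export
fit_mcmc <- function(spec, design, outcomes, C, chains = 4, draws = 1000,
                     warmup = NULL, seed = 1, obs_weights = NULL,
                     base_steps = 24) {
  X <- as.matrix(design)
  Xarr <- array(X, dim = c(nrow(X), ncol(X), 1))
  fit_engine(spec, Xarr, outcomes, C, chains = chains, draws = draws,
             warmup = warmup, seed = seed, obs_weights = obs_weights,
             base_steps = base_steps)
}

# Shared engine; Xarr is S x P x M (M > 1 = mixture pooling over imputations).
fit_engine <- function(spec, Xarr, outcomes, C, chains = 4, draws = 1000,
                       warmup = NULL, seed = 1, obs_weights = NULL,
                       base_steps = 24) {
  stopifnot(inherits(spec, "model_spec"))
  if (chains < 2) stop("need at least 2 chains", call. = FALSE)
  if (is.null(warmup)) warmup <- max(300L, draws %/% 2L)
  Y <- extract_outcomes(outcomes, spec)
  S <- nrow(Y); K <- ncol(Y); P <- dim(Xarr)[2]
  stopifnot(dim(Xarr)[1] == S, nrow(C) == S, P == length(spec$predictors))
  if (is.null(obs_weights)) obs_weights <- matrix(1, S, K)
  storage.mode(obs_weights) <- "double"

  B <- phylo_factor_of(C)
  E <- ncol(B)
  dims <- param_dims(S, K, P, E)
  tmb_data <- list(
    Y = Y, X = Xarr, B = B, W = obs_weights,
    s_alpha = spec$s_alpha, s_beta = spec$s_beta, s_sd = spec$s_sd,
    lkj_eta = spec$lkj_eta, use_u = as.integer(spec$use_society_effect)
  )
  obj <- TMB::MakeADFun(data = tmb_data, parameters = param_skeleton(S, K, P, E),
                        DLL = "punishr", silent = TRUE)
  fn <- function(theta) {
    v <- -as.numeric(obj$fn(theta))
    if (is.na(v)) -Inf else v
  }
  gr <- function(theta) -as.vector(obj$gr(theta))

  any_obs <- colSums(obs_weights) > 0
  p_hat <- ifelse(any_obs, pmin(pmax(colMeans(Y), 0.05), 0.95), 0.5)
  base_init <- unlist(param_skeleton(S, K, P, E), use.names = FALSE)
  alpha_idx <- seq_len(K)
  sd_idx <- K + K * P + seq_len(2 * K)

  all_draws <- vector("list", chains)
  chain_meta <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed((seed + 7919L * ch) %% .Machine$integer.max)
    init <- base_init
    init[alpha_idx] <- stats::qlogis(p_hat)
    init[sd_idx] <- log(0.3)
    init <- init + stats::rnorm(dims$D, 0, 0.02)
    res <- hmc_chain(fn, gr, init, n_warmup = warmup, n_draws = draws,
                     base_steps = base_steps)
    all_draws[[ch]] <- res$draws
    chain_meta[[ch]] <- res[c("accept_rate", "n_divergent", "step_size")]
  }
  raw <- do.call(rbind, all_draws)
  chain_id <- rep(seq_len(chains), each = draws)

  fit <- structure(
    list(
      draws = unpack_draws(raw, B, spec, S, K, P),
      raw = raw, chain_id = chain_id,
      spec = spec, outcome_names = colnames(Y), predictor_names = spec$predictors,
      taxa = rownames(C), n_chains = chains, n_draws = draws, warmup = warmup,
      n_params = dims$D, seed = seed, chain_meta = chain_meta
    ),
    class = "punish_fit"
  )
  fit$diagnostics <- fit_diagnostics(fit)
  fit$raw <- NULL  # keep the object lean; draws list retains everything needed
  fit
}

extract_outcomes <- function(outcomes, spec) {
  Y <- if (inherits(outcomes, "evidence_matrix")) outcomes$punishments else as.matrix(outcomes)
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y))) colnames(Y) <- spec$outcomes
  missing_out <- setdiff(spec$outcomes, colnames(Y))
  if (length(missing_out) > 0) {
    stop("outcomes not found: ", paste(missing_out, collapse = ", "), call. = FALSE)
  }
  Y[, spec$outcomes, drop = FALSE]
}

# Exact factor of the correlation: the sparse root-path factor when the
# source tree travelled with the matrix, otherwise its dense Cholesky.
phylo_factor_of <- function(C) {
  tree <- attr(C, "tree")
  if (!is.null(tree)) {
    phylo_factor(tree, taxa_order = rownames(C))
  } else {
    Matrix::Matrix(t(chol(unclass(C))), sparse = TRUE)
  }
}

# Convert the flat draw matrix to labelled arrays on the centred scale.
unpack_draws <- function(raw, B, spec, S, K, P) {
  n <- nrow(raw)
  E <- ncol(B)
  out <- list(
    alpha = matrix(NA_real_, n, K), beta = array(NA_real_, c(n, K, P)),
    sigma_phylo = matrix(NA_real_, n, K), tau = matrix(NA_real_, n, K),
    Omega = array(NA_real_, c(n, K, K)),
    phi = array(NA_real_, c(n, S, K)), u = array(NA_real_, c(n, S, K))
  )
  for (i in seq_len(n)) {
    nc <- split_theta(raw[i, ], S, K, P, E)
    cp <- centre_params(nc, B)
    out$alpha[i, ] <- cp$alpha
    out$beta[i, , ] <- cp$beta
    out$sigma_phylo[i, ] <- cp$sigma_phylo
    out$tau[i, ] <- cp$tau
    out$Omega[i, , ] <- cp$Omega
    out$phi[i, , ] <- cp$phi
    out$u[i, , ] <- cp$u
  }
  colnames(out$alpha) <- colnames(out$sigma_phylo) <- colnames(out$tau) <- spec$outcomes
  dimnames(out$beta) <- list(NULL, spec$outcomes, spec$predictors)
  dimnames(out$Omega) <- list(NULL, spec$outcomes, spec$outcomes)
  out
}

#' @export
print.punish_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<punish_fit> %d outcomes x %d predictors, %d chains x %d draws\n",
    length(x$outcome_names), length(x$predictor_names), x$n_chains, x$n_draws))
  cat(sprintf("  max R-hat %.3f | min ESS %.0f | divergent %d (%.1f%%)\n",
              d$max_rhat, d$min_ess, d$n_divergent, 100 * d$divergence_rate))
  if (length(d$flags) > 0) cat("  flags:", paste(d$flags, collapse = "; "), "\n")
  invisible(x)
}

# Split R-hat (each chain halved) for every scalar column, ESS for the
# structural parameters, divergence bookkeeping; flags per the fit contract.
fit_diagnostics <- function(fit) {
  raw <- fit$raw
  chain_id <- fit$chain_id
  K <- length(fit$outcome_names); P <- length(fit$predictor_names)
  n_struct <- K + K * P + 2 * K + max(1L, K * (K - 1L) / 2L)
  rhat <- split_rhat(raw, chain_id)
  ess <- vapply(seq_len(n_struct), function(j) {
    sum(vapply(unique(chain_id), function(ch) {
      as.numeric(coda::effectiveSize(raw[chain_id == ch, j]))
    }, numeric(1)))
  }, numeric(1))
  n_div <- sum(vapply(fit$chain_meta, function(m) m$n_divergent, numeric(1)))
  div_rate <- n_div / nrow(raw)
  rhat_structural <- max(rhat[seq_len(n_struct)], na.rm = TRUE)
  flags <- character(0)
  if (max(rhat, na.rm = TRUE) > 1.01) {
    flags <- c(flags, sprintf("%d parameters with R-hat > 1.01", sum(rhat > 1.01, na.rm = TRUE)))
  }
  if (min(ess) < 400) {
    flags <- c(flags, sprintf("%d structural parameters with ESS < 400", sum(ess < 400)))
  }
  if (div_rate > 0.05) {
    warning(sprintf("divergence rate %.1f%% exceeds 5%%", 100 * div_rate), call. = FALSE)
    flags <- c(flags, sprintf("divergence rate %.1f%%", 100 * div_rate))
  }
  list(rhat = rhat, ess = ess, max_rhat = max(rhat, na.rm = TRUE),
       max_rhat_structural = rhat_structural,
       min_ess = min(ess), n_divergent = n_div, divergence_rate = div_rate,
       flags = flags)
}

split_rhat <- function(draws, chain_id) {
  chains <- unique(chain_id)
  pieces <- list()
  for (ch in chains) {
    idx <- which(chain_id == ch)
    h <- length(idx) %/% 2
    pieces <- c(pieces, list(idx[seq_len(h)], idx[(h + 1):(2 * h)]))
  }
  m <- length(pieces)
  n <- length(pieces[[1]])
  apply(draws, 2, function(x) {
    means <- vapply(pieces, function(ix) mean(x[ix]), numeric(1))
    vars <- vapply(pieces, function(ix) stats::var(x[ix]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Posterior of the phylogenetic-signal variance proportion
#'
#' For each posterior draw and outcome, the share of latent (logit-scale)
#' non-fixed variance attributable to phylogeny:
#' `sigma_phylo^2 / (sigma_phylo^2 + tau^2 + pi^2/3)`, where `pi^2/3` is the
#' residual variance of the standard logistic distribution. The denominator
#' includes the society-level effect so the proportion partitions the full
#' latent non-fixed variance.
#'
#' @param fit a `punish_fit`.
#' @return draws x K matrix of variance proportions in `[0, 1]`.
#' @export
phylogenetic_signal <- function(fit) {
  stopifnot(inherits(fit, "punish_fit"))
  s2 <- fit$draws$sigma_phylo^2
  # with the society effect disabled its (prior-only) draws play no role
  t2 <- if (isTRUE(fit$spec$use_society_effect)) fit$draws$tau^2 else 0
  sig <- s2 / (s2 + t2 + pi^2 / 3)
  colnames(sig) <- fit$outcome_names
  sig
}

#' Fit the model across multiply-imputed tables
#'
#' Executes a [pool_for_fitting()] plan. Under `"concatenate"` the model is
#' fitted once per completed table with an equal share of the requested draws
#' and the posteriors are concatenated; under `"mixture"` a single fit
#' averages the likelihood over tables at every evaluation.
#'
#' @param spec a [model_spec()].
#' @param plan a `fit_plan` from [pool_for_fitting()].
#' @param docs document metadata (for meta-ethnographic covariates).
#' @param outcomes S x K binary matrix or [evidence_matrix].
#' @param C phylogenetic correlation matrix.
#' @param chains,draws,warmup,seed,base_steps as in [fit_mcmc()]; `draws` is
#'   the total pooled posterior size per chain under concatenation.
#' @return a `punish_fit` whose draws pool across imputations.
#' @export
fit_pooled <- function(spec, plan, docs, outcomes, C, chains = 2, draws = 1000,
                       warmup = NULL, seed = 1, base_steps = 24) {
  stopifnot(inherits(plan, "fit_plan"))
  taxa <- rownames(C)
  if (plan$strategy == "mixture") {
    Xs <- lapply(plan$tables, function(tab) build_design(tab, docs, spec, taxa))
    Xarr <- array(unlist(Xs), dim = c(nrow(Xs[[1]]), ncol(Xs[[1]]), plan$m))
    return(fit_engine(spec, Xarr, outcomes, C, chains = chains, draws = draws,
                      warmup = warmup, seed = seed, base_steps = base_steps))
  }
  per_table <- max(150L, ceiling(draws / plan$m))
  fits <- vector("list", plan$m)
  for (t in seq_len(plan$m)) {
    X <- build_design(plan$tables[[t]], docs, spec, taxa)
    fits[[t]] <- fit_mcmc(spec, X, outcomes, C, chains = chains,
                          draws = per_table, warmup = warmup,
                          seed = seed + t, base_steps = base_steps)
  }
  concat_fits(fits)
}

# Concatenate posterior draws of structurally identical fits.
concat_fits <- function(fits) {
  f1 <- fits[[1]]
  if (length(fits) == 1) return(f1)
  bind <- function(name) {
    parts <- lapply(fits, function(f) f$draws[[name]])
    if (length(dim(parts[[1]])) == 2) do.call(rbind, parts)
    else {
      arr <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                               dim(parts[[1]])[-1]))
      at <- 0L
      for (p in parts) {
        arr[at + seq_len(dim(p)[1]), , ] <- p
        at <- at + dim(p)[1]
      }
      dimnames(arr) <- dimnames(parts[[1]])
      arr
    }
  }
  f1$draws <- stats::setNames(lapply(names(f1$draws), bind), names(f1$draws))
  f1$chain_id <- unlist(lapply(seq_along(fits), function(i) {
    fits[[i]]$chain_id + (i - 1) * fits[[i]]$n_chains
  }))
  f1$n_draws <- sum(vapply(fits, function(f) f$n_draws, numeric(1)))
  f1$pooled_over <- length(fits)
  div <- sum(vapply(fits, function(f) f$diagnostics$n_divergent, numeric(1)))
  f1$diagnostics <- list(
    rhat = do.call(pmax, lapply(fits, function(f) f$diagnostics$rhat)),
    ess = Reduce(`+`, lapply(fits, function(f) f$diagnostics$ess)),
    max_rhat = max(vapply(fits, function(f) f$diagnostics$max_rhat, numeric(1))),
    max_rhat_structural = max(vapply(fits, function(f) f$diagnostics$max_rhat_structural, numeric(1))),
    min_ess = sum(vapply(fits, function(f) f$diagnostics$min_ess, numeric(1))),
    n_divergent = div,
    divergence_rate = div / sum(vapply(fits, function(f) f$n_draws * f$n_chains, numeric(1))),
    flags = unique(unlist(lapply(fits, function(f) f$diagnostics$flags)))
  )
  f1
}

#' Fit the meta-ethnographic bias model
#'
#' Same model family as [fit_mcmc()], with the three document-level
#' covariates (z-scored log page count, z-scored publication year, female
#' coauthor present) replacing the socioecological predictor set.
#'
#' @param docs document metadata data.frame (complete).
#' @param outcomes S x K binary matrix or [evidence_matrix].
#' @param C phylogenetic correlation matrix.
#' @inheritParams fit_mcmc
#' @return a `punish_fit`.
#' @export
fit_bias_model <- function(docs, outcomes, C, chains = 4, draws = 1000,
                           warmup = NULL, seed = 1, base_steps = 24,
                           spec = NULL) {
  Y <- if (inherits(outcomes, "evidence_matrix")) outcomes$punishments else as.matrix(outcomes)
  if (is.null(spec)) {
    spec <- model_spec(outcomes = colnames(Y),
                       predictors = c("log_pages", "pub_year", "female_coauthor"))
  }
  if (anyNA(docs[c("page_count", "pub_year", "female_coauthor")])) {
    stop("document metadata must be complete for the bias model", call. = FALSE)
  }
  X <- build_design(NULL, docs, spec, taxa_order = rownames(C))
  fit_mcmc(spec, X, outcomes, C, chains = chains, draws = draws,
           warmup = warmup, seed = seed, base_steps = base_steps)
}
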