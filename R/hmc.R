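# Hamiltonian Monte Carlo with dual-averaging step-size adaptation and
# diagonal mass-matrix estimation during warmup. `fn(theta)` returns the log
# density, `gr(theta)` its gradient; gradients alone drive the leapfrog
# integrator and the density is evaluated only at trajectory ends. Kept
# generic so the sampler can be validated on closed-form targets.
hmc_chain <- function(fn, gr, init, n_warmup, n_draws,
                      target_accept = 0.8, base_steps = 12,
                      max_divergence_delta = 500) {
  D <- length(init)
  theta <- init
  cur_lp <- fn(theta)
  if (!is.finite(cur_lp)) stop("non-finite log-density at initial value", call. = FALSE)
  cur_gr <- gr(theta)

  inv_mass <- rep(1, D)
  sqrt_mass <- rep(1, D)

  # dual-averaging state (Hoffman & Gelman defaults)
  da_init <- function(eps0) {
    list(eps = eps0, log_eps_bar = log(eps0), h_bar = 0,
         mu = log(10 * eps0), t = 0, gamma = 0.05, t0 = 10, kappa = 0.75)
  }
  da_update <- function(da, accept_prob) {
    da$t <- da$t + 1
    frac <- 1 / (da$t + da$t0)
    da$h_bar <- (1 - frac) * da$h_bar + frac * (target_accept - accept_prob)
    log_eps <- da$mu - sqrt(da$t) / da$gamma * da$h_bar
    w <- da$t^(-da$kappa)
    da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
    da$eps <- exp(log_eps)
    da
  }

  # crude initial step size: shrink until a single leapfrog step is stable
  eps <- 0.1
  for (try in 1:12) {
    p0 <- stats::rnorm(D) * sqrt_mass
    st <- leapfrog(fn, gr, theta, p0, cur_gr, eps, 1, inv_mass)
    h0 <- -cur_lp + 0.5 * sum(p0^2 * inv_mass)
    if (is.finite(st$h) && abs(st$h - h0) < 1) break
    eps <- eps / 2
  }
  da <- da_init(eps)

  phase1 <- max(10L, floor(0.15 * n_warmup))
  phase2 <- max(20L, floor(0.75 * n_warmup))  # end of variance accumulation
  acc_n <- 0L
  acc_mean <- numeric(D)
  acc_m2 <- numeric(D)

  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, D)
  n_div <- 0L
  n_acc <- 0
  for (it in seq_len(total)) {
    L <- sample(max(1L, floor(0.8 * base_steps)):ceiling(1.2 * base_steps), 1L)
    p0 <- stats::rnorm(D) * sqrt_mass
    h0 <- -cur_lp + 0.5 * sum(p0^2 * inv_mass)
    st <- leapfrog(fn, gr, theta, p0, cur_gr, da$eps, L, inv_mass)
    delta <- st$h - h0
    diverged <- !is.finite(delta) || delta > max_divergence_delta
    accept_prob <- if (!is.finite(delta)) 0 else min(1, exp(-delta))
    if (!diverged && stats::runif(1) < accept_prob) {
      theta <- st$theta
      cur_lp <- st$lp
      cur_gr <- st$grad
    }
    if (diverged && it > n_warmup) n_div <- n_div + 1L
    if (it > n_warmup) n_acc <- n_acc + accept_prob

    if (it <= n_warmup) {
      da <- da_update(da, accept_prob)
      if (it > phase1 && it <= phase2) {
        acc_n <- acc_n + 1L
        d0 <- theta - acc_mean
        acc_mean <- acc_mean + d0 / acc_n
        acc_m2 <- acc_m2 + d0 * (theta - acc_mean)
      }
      if (it == phase2 && acc_n > 10L) {
        v <- acc_m2 / (acc_n - 1)
        # regularise towards unit scale (Stan-style shrinkage)
        v <- (acc_n / (acc_n + 5)) * v + (5 / (acc_n + 5)) * 1e-3
        inv_mass <- pmax(v, 1e-8)
        sqrt_mass <- 1 / sqrt(inv_mass)
        da <- da_init(exp(da$log_eps_bar))
      }
      if (it == n_warmup) da$eps <- exp(da$log_eps_bar)
    } else {
      draws[it - n_warmup, ] <- theta
    }
  }
  list(draws = draws, accept_rate = n_acc / n_draws, n_divergent = n_div,
       step_size = da$eps, inv_mass = inv_mass)
}

leapfrog <- function(fn, gr, theta, p, g, eps, n_steps, inv_mass) {
  for (l in seq_len(n_steps)) {
    p <- p + 0.5 * eps * g
    theta <- theta + eps * (p * inv_mass)
    g <- gr(theta)
    if (!all(is.finite(g))) {
      return(list(theta = theta, lp = -Inf, grad = g, h = Inf))
    }
    p <- p + 0.5 * eps * g
  }
  lp <- fn(theta)
  if (!is.finite(lp)) {
    return(list(theta = theta, lp = -Inf, grad = g, h = Inf))
  }
  list(theta = theta, lp = lp, grad = g,
       h = -lp + 0.5 * sum(p^2 * inv_mass))
}
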