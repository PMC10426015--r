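#define TMB_LIB_INIT R_init_punishr
#include <TMB.hpp>

// Joint negative log-posterior of the multi-response phylogenetic logistic
// regression, in the non-centred parameterisation:
//
//   y[s,k] ~ Bernoulli(inv_logit(alpha_k + x_s' beta_k + sigma_k*phi[s,k]
//                                 + tau_k*u[s,k]))
//   phi[,k] = B z_phi[,k],    z_phi ~ N(0,1)   (phylogenetic effect)
//   u[s,]  = L_Omega z_u[s,], z_u  ~ N(0,1)    (correlated society effect)
//
// with priors N(0,s_alpha) / N(0,s_beta) on intercepts and slopes,
// half-N(0,s_sd) on sigma and tau (sampled as logs, Jacobian included), and
// LKJ(eta) on the correlation Omega via the canonical-partial-correlation
// (tanh) transform of the unconstrained vector omega_raw.
//
// X may hold M >= 1 completed design matrices (multiple imputation); with
// M > 1 the likelihood is the average over tables of the full-table
// likelihood ("mixture" pooling). W holds 0/1 observation weights; setting
// all weights to zero yields prior-only sampling.
template<class Type>
Type objective_function<Type>::operator() ()
{
  DATA_MATRIX(Y);        // S x K binary outcomes
  DATA_ARRAY(X);         // S x P x M design array
  DATA_SPARSE_MATRIX(B); // S x E factor of the phylo correlation (C = B B')
  DATA_MATRIX(W);        // S x K observation weights (0/1)
  DATA_SCALAR(s_alpha);
  DATA_SCALAR(s_beta);
  DATA_SCALAR(s_sd);
  DATA_SCALAR(lkj_eta);
  DATA_INTEGER(use_u);   // 0 disables the society-level effect

  PARAMETER_VECTOR(alpha);      // K
  PARAMETER_MATRIX(beta);       // K x P
  PARAMETER_VECTOR(log_sigma);  // K
  PARAMETER_VECTOR(log_tau);    // K
  PARAMETER_VECTOR(omega_raw);  // K(K-1)/2 (length 1 dummy when K = 1)
  PARAMETER_MATRIX(z_phi);      // E x K
  PARAMETER_MATRIX(z_u);        // S x K

  int S = Y.rows(), K = Y.cols();
  int P = X.dim(1), M = X.dim(2);
  Type lp = 0;

  vector<Type> sigma = exp(log_sigma);
  vector<Type> tau = exp(log_tau);

  // --- priors ---------------------------------------------------------
  for (int k = 0; k < K; k++) {
    lp += dnorm(alpha(k), Type(0), s_alpha, true);
    for (int p = 0; p < P; p++) lp += dnorm(beta(k, p), Type(0), s_beta, true);
    // half-normal on the SD scale + log-Jacobian of the log transform
    lp += dnorm(sigma(k), Type(0), s_sd, true) + log(Type(2)) + log_sigma(k);
    lp += dnorm(tau(k), Type(0), s_sd, true) + log(Type(2)) + log_tau(k);
  }
  // standard-normal priors on the non-centred deviates
  int E = B.cols();
  lp += -Type(0.5) * (z_phi.array().square().sum() + z_u.array().square().sum())
        - Type(0.5) * Type((E + S) * K) * log(Type(2) * M_PI);

  // --- LKJ(eta) prior on Omega via its Cholesky factor -----------------
  matrix<Type> LOm(K, K);
  LOm.setZero();
  LOm(0, 0) = Type(1);
  if (K > 1) {
    int idx = 0;
    for (int i = 1; i < K; i++) {
      Type sumsq = 0;
      for (int j = 0; j < i; j++) {
        Type z = tanh(omega_raw(idx++));
        Type w2 = Type(1) - sumsq;
        LOm(i, j) = z * sqrt(w2);
        // log-Jacobian of the tanh CPC transform, row by row
        lp += log(Type(1) - z * z) + Type(0.5) * log(w2);
        sumsq += LOm(i, j) * LOm(i, j);
      }
      LOm(i, i) = sqrt(Type(1) - sumsq);
      // LKJ density on the Cholesky factor: sum over rows i (1-based row r)
      // of (K - r + 2 eta - 2) log L_rr
      lp += (Type(K - (i + 1)) + Type(2) * lkj_eta - Type(2)) * log(LOm(i, i));
    }
  } else {
    lp += dnorm(omega_raw(0), Type(0), Type(1), true);  // inert dummy
  }

  // --- random effects ---------------------------------------------------
  // sparse root-path factor: one tape entry per (leaf, ancestor edge) pair
  matrix<Type> Phi = B * z_phi;                        // S x K
  matrix<Type> U(S, K);
  if (use_u) {
    matrix<Type> LOmT = LOm.transpose();
    U = atomic::matmul(z_u, LOmT);
  } else U.setZero();

  // --- likelihood, averaged over the M completed tables ----------------
  vector<Type> ll(M);
  for (int m = 0; m < M; m++) {
    matrix<Type> Xm(S, P);
    for (int s = 0; s < S; s++)
      for (int p = 0; p < P; p++) Xm(s, p) = X(s, p, m);
    matrix<Type> betaT = beta.transpose();               // P x K
    matrix<Type> Xb = atomic::matmul(Xm, betaT);         // S x K
    Type llm = 0;
    for (int s = 0; s < S; s++) {
      for (int k = 0; k < K; k++) {
        Type eta = alpha(k) + sigma(k) * Phi(s, k) + Xb(s, k);
        if (use_u) eta += tau(k) * U(s, k);
        llm += W(s, k) * dbinom_robust(Y(s, k), Type(1), eta, true);
      }
    }
    ll(m) = llm;
  }
  if (M == 1) {
    lp += ll(0);
  } else {
    Type mx = ll(0);
    for (int m = 1; m < M; m++) mx = CppAD::CondExpGt(ll(m), mx, ll(m), mx);
    Type acc = 0;
    for (int m = 0; m < M; m++) acc += exp(ll(m) - mx);
    lp += mx + log(acc) - log(Type(M));
  }

  return -lp;
}
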