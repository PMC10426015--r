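# punishr

Bayesian phylogenetic analysis of cross-cultural punishment systems.

Comparative anthropology asks how the punishments societies apply to norm
violations — reputational damage, material fines, physical sanctions,
execution — covary with socioecology: external trade, animal husbandry,
dependence on hunting, food storage, community size, and social
stratification. Societies inherit institutions from common cultural
ancestors, so they are not independent observations (Galton's problem).
punishr packages the full analysis for this kind of study:

* **Descriptive evidence statistics** over a society × (norm-violation,
  punishment-type) coding table: prevalences, violation/punishment
  co-occurrence (phi and Jaccard), and the 5 × 4 cross-tabulation.
* **Multiple imputation** of missing socioecological predictors by chained
  equations (bootstrap logistic draws for binary variables, predictive mean
  matching for ordinals), with pooling of imputations into the fit.
* **A multi-response Bayesian phylogenetic logistic regression**: for
  society *s* and punishment type *k*,

  ```
  y[s,k] ~ Bernoulli( inv_logit( alpha_k + x_s' beta_k + phi[s,k] + u[s,k] ) )
  phi[,k] ~ MVN(0, sigma_k^2 C)                      # phylogenetic effect
  u[s,]  ~ MVN(0, diag(tau) Omega diag(tau))         # correlated society effect
  ```

  with C the Brownian-motion correlation matrix of the cultural supertree,
  weakly regularising priors (normal(0, 2.5) intercepts/slopes,
  half-normal(0, 1.5) SDs, LKJ(2) on Omega), and the latent-scale
  phylogenetic signal `sigma_k^2 / (sigma_k^2 + tau_k^2 + pi^2/3)`.
* **Posterior summaries**: medians, 90% highest-density intervals,
  probability of direction, and strong/moderate/weak evidence classes.
* **A synthetic-study generator** with known ground truth (tree, documents,
  predictors with missingness, outcomes), so the whole pipeline is testable
  without any external data.

The model's log-posterior is compiled with automatic differentiation (TMB)
and sampled by the package's Hamiltonian Monte Carlo implementation
(non-centred parameterisation, dual-averaging step size, adaptive diagonal
mass matrix), with split R-hat, ESS, and divergence diagnostics.

## Worked example

```r
library(punishr)

# a complete synthetic study: 131 societies, supertree, coded evidence,
# six predictors with ~3% missing cells, known generating truth
fx <- make_study_fixture(seed = 1)
C  <- phylo_corr(fx$tree)

prevalence(fx$evidence, "adultery")
#> [1] 0.6870229
cooccurrence_stats(fx$evidence)$mean_jaccard
#> [1] 0.6531361

# impute missing predictors and fit the 4-outcome phylogenetic model,
# pooling over 20 completed tables
imp  <- impute_chained(fx$socio, m = 20, seed = 2)
plan <- pool_for_fitting(imp, "concatenate")
fit  <- fit_pooled(model_spec(), plan, fx$docs,
                   fx$evidence$punishments[rownames(C), ], C,
                   chains = 2, draws = 1000, warmup = 300, seed = 3)

head(summarize_effects(fit), 3)
#>        outcome          predictor    median  hpdi90_lo hpdi90_hi        pd    class
#> 1 reputational     external_trade 0.5886281 -0.9999668 1.9784826 0.7376667     weak
#> 2 reputational   animal_husbandry 0.1587430 -0.6817560 0.9453906 0.6281667     weak
#> 3 reputational dependence_hunting 0.6866101 -0.1273229 1.5652817 0.9266667 moderate

apply(phylogenetic_signal(fit), 2, median)
#> reputational     material     physical    execution
#>   0.04760254   0.35139998   0.19923535   0.27929477
```

`summarize_effects()` rows are posterior median log-odds per
outcome × predictor with their 90% HPDI, the probability of direction
(how much of the posterior shares the median's sign), and the evidence
class ("strong" if the 90% HPDI excludes zero, "moderate" if the 80% one
does). The signal numbers are posterior medians of the share of latent
variance attributable to phylogeny — weak-to-moderate here against a
generating truth of 0.04–0.17 (the latent scale of this model family is
only weakly identified from one observation per society and outcome; the
methods vignette discusses this at length).

A YAML-configured pipeline (`run_config()`, `cmd_describe()`, `cmd_fit()`,
`cmd_recover()`) and a thin CLI wrapper (`inst/cli/punishr.R` with
subcommands simulate / describe / impute / fit / recover) wire these stages
together; see the methods vignette (`vignettes/methods.Rmd`) for the model,
its assumptions, and the design decisions.

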