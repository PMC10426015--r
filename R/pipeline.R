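#' Build a pipeline run configuration
#'
#' A serialisable record of everything a run needs: seeds, imputation count,
#' MCMC profile, prior scales, covariate set, pooling strategy, and paths.
#' `profile = "test"` uses 2 chains x 500 draws (400 warmup); `"full"`
#' uses 4 chains x 1000 (500 warmup).
#'
#' @param coding_csv input coding-table CSV (omit for simulated runs).
#' @param tree_file input Newick file (omit to use a simulated tree).
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param m number of imputations. Default 20.
#' @param profile `"test"` or `"full"`.
#' @param covariate_set `"socioecological"`, `"bias"`, or one punishment-type
#'   name for a univariate-response fit.
#' @param pooling `"concatenate"` or `"mixture"`.
#' @param s_alpha,s_beta,s_sd,lkj_eta prior settings (see [model_spec()]).
#' @param n_replicates replicate count for [cmd_recover()].
#' @param truth_preset truth preset name for simulated runs.
#' @param n_societies simulated sample size.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(coding_csv = NULL, tree_file = NULL, out_dir = "punishr_out",
                       seed = 1, m = 20, profile = c("test", "full"),
                       covariate_set = "socioecological",
                       pooling = c("concatenate", "mixture"),
                       s_alpha = 2.5, s_beta = 2.5, s_sd = 1.5, lkj_eta = 2,
                       n_replicates = 20, truth_preset = "study",
                       n_societies = 131) {
  profile <- match.arg(profile)
  pooling <- match.arg(pooling)
  ok_sets <- c("socioecological", "bias", punishment_types())
  if (!covariate_set %in% ok_sets) {
    stop("covariate_set must be one of: ", paste(ok_sets, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(coding_csv = coding_csv, tree_file = tree_file, out_dir = out_dir,
         seed = seed, m = m, profile = profile, covariate_set = covariate_set,
         pooling = pooling, s_alpha = s_alpha, s_beta = s_beta, s_sd = s_sd,
         lkj_eta = lkj_eta, n_replicates = n_replicates,
         truth_preset = truth_preset, n_societies = n_societies),
    class = "run_config"
  )
}

#' Read / write a run configuration (YAML)
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

mcmc_profile <- function(profile) {
  if (profile == "full") list(chains = 4L, draws = 1000L, warmup = 500L)
  else list(chains = 2L, draws = 500L, warmup = 400L)
}

start_run <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(config$out_dir, "resolved_config.yaml"))
  logf <- file.path(config$out_dir, "run_log.txt")
  log_line(logf, sprintf("punishr %s | R %s | seed %d",
                         as.character(utils::packageVersion("punishr")),
                         paste(R.version$major, R.version$minor, sep = "."),
                         config$seed))
  logf
}

log_line <- function(logf, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = logf, append = TRUE)
  invisible(line)
}

#' Descriptive-statistics report for a coding table
#'
#' Reads and validates the coding table, then writes the prevalence table
#' (9 evidence flags plus the any-violation / any-punishment aggregates), the
#' per-domain co-occurrence statistics, and the 5 x 4 cross-tabulation as
#' CSVs under `out_dir`.
#'
#' @param coding_csv coding-table CSV path.
#' @param out_dir output directory.
#' @return (invisibly) list with `prevalence`, `cooccurrence`, `crosstab`.
#' @export
cmd_describe <- function(coding_csv, out_dir) {
  dat <- read_coding_table(coding_csv)
  em <- dat$evidence
  vars <- c(violation_domains(), punishment_types(),
            "any_violation", "any_punishment")
  prev <- data.frame(
    variable = vars,
    prevalence = vapply(vars, function(v) prevalence(em, v), numeric(1)),
    row.names = NULL
  )
  co <- cooccurrence_stats(em)
  xt <- crosstab_counts(em)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(prev, file.path(out_dir, "prevalence.csv"), row.names = FALSE)
  utils::write.csv(co$per_domain, file.path(out_dir, "cooccurrence.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(domain = rownames(xt), xt, check.names = FALSE),
                   file.path(out_dir, "crosstab.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mean_phi = co$mean_phi, mean_jaccard = co$mean_jaccard,
         min_phi = co$min_phi, max_phi = co$max_phi),
    file.path(out_dir, "cooccurrence_summary.json"), auto_unbox = TRUE,
    digits = NA
  )
  invisible(list(prevalence = prev, cooccurrence = co, crosstab = xt))
}

#' Simulate a study to disk
#'
#' @param config a [run_config()]; uses `seed`, `truth_preset`,
#'   `n_societies`, `out_dir`.
#' @return (invisibly) the fixture.
#' @export
cmd_simulate <- function(config) {
  fx <- make_study_fixture(seed = config$seed, n = config$n_societies,
                           truth = punish_truth(config$truth_preset))
  write_study_fixture(fx, config$out_dir)
  write_config(config, file.path(config$out_dir, "resolved_config.yaml"))
  invisible(fx)
}

#' Impute, fit, and summarise in one pass
#'
#' Reads the coding table and tree named by the config (or simulates a study
#' when neither is given), imputes the missing predictor cells, fits the
#' requested model over the imputations, and writes posterior summaries,
#' signal estimates, draws of the structural parameters, and diagnostics
#' under `out_dir`. Fails (returns `ok = FALSE`) if any split R-hat exceeds
#' 1.05.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `fit`, `summary`, `signal`, `diagnostics`,
#'   `ok`.
#' @export
cmd_fit <- function(config) {
  if (!is.null(config$coding_csv) && !file.exists(config$coding_csv)) {
    stop("input file not found: ", config$coding_csv, call. = FALSE)
  }
  if (!is.null(config$tree_file) && !file.exists(config$tree_file)) {
    stop("input file not found: ", config$tree_file, call. = FALSE)
  }
  logf <- start_run(config)
  prof <- mcmc_profile(config$profile)

  if (is.null(config$coding_csv)) {
    log_line(logf, "no coding table given; simulating a study fixture")
    fx <- make_study_fixture(seed = config$seed, n = config$n_societies,
                             truth = punish_truth(config$truth_preset))
    docs <- fx$docs; em <- fx$evidence; socio <- fx$socio; tree <- fx$tree
  } else {
    dat <- read_coding_table(config$coding_csv)
    docs <- dat$docs; em <- dat$evidence; socio <- dat$socio
    tree <- parse_newick(paste(readLines(config$tree_file), collapse = ""))
    tree <- prune_to_taxa(tree, docs$society_id)
  }
  C <- phylo_corr(tree)
  ord <- rownames(C)

  t0 <- Sys.time()
  if (config$covariate_set == "bias") {
    log_line(logf, "fitting meta-ethnographic bias model")
    spec <- model_spec(outcomes = punishment_types(),
                       predictors = c("log_pages", "pub_year", "female_coauthor"),
                       s_alpha = config$s_alpha, s_beta = config$s_beta,
                       s_sd = config$s_sd, lkj_eta = config$lkj_eta)
    docs_o <- docs[match(ord, docs$society_id), ]
    Y <- em$punishments[ord, , drop = FALSE]
    fit <- fit_bias_model(docs_o, Y, C, chains = prof$chains,
                          draws = prof$draws, warmup = prof$warmup,
                          seed = config$seed, spec = spec)
  } else {
    outs <- if (config$covariate_set == "socioecological") punishment_types()
            else config$covariate_set
    spec <- model_spec(outcomes = outs,
                       s_alpha = config$s_alpha, s_beta = config$s_beta,
                       s_sd = config$s_sd, lkj_eta = config$lkj_eta)
    log_line(logf, sprintf("imputing m = %d tables", config$m))
    imp <- impute_chained(socio, m = config$m, seed = config$seed)
    plan <- pool_for_fitting(imp, config$pooling)
    log_line(logf, sprintf("fitting %s model over %d imputations (%s pooling)",
                           paste(outs, collapse = "/"), config$m, config$pooling))
    Y <- em$punishments[ord, outs, drop = FALSE]
    fit <- fit_pooled(spec, plan, docs, Y, C, chains = prof$chains,
                      draws = prof$draws, warmup = prof$warmup,
                      seed = config$seed)
  }
  log_line(logf, sprintf("fit finished in %.1f s",
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  summ <- summarize_effects(fit)
  write_effect_summary(summ, file.path(config$out_dir, "effect_summary.csv"))
  sig <- phylogenetic_signal(fit)
  sig_summary <- data.frame(
    outcome = colnames(sig),
    median = apply(sig, 2, stats::median),
    hpdi90_lo = apply(sig, 2, function(s) hpdi(s, 0.9)[[1]]),
    hpdi90_hi = apply(sig, 2, function(s) hpdi(s, 0.9)[[2]]),
    row.names = NULL
  )
  utils::write.csv(sig_summary, file.path(config$out_dir, "signal_summary.csv"),
                   row.names = FALSE)
  write_draws_csv(fit, file.path(config$out_dir, "draws.csv"))
  diag <- fit$diagnostics
  jsonlite::write_json(
    list(max_rhat = diag$max_rhat,
         max_rhat_structural = diag$max_rhat_structural,
         min_ess = diag$min_ess,
         n_divergent = diag$n_divergent, divergence_rate = diag$divergence_rate,
         flags = diag$flags),
    file.path(config$out_dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA
  )
  # convergence gate on the structural (reported) parameters; the latent
  # deviates' split R-hat is noise-dominated for short pooled segments
  ok <- diag$max_rhat_structural <= 1.05
  if (!ok) {
    log_line(logf, sprintf("FAIL: structural max R-hat %.3f > 1.05",
                           diag$max_rhat_structural))
  }
  invisible(list(fit = fit, summary = summ, signal = sig_summary,
                 diagnostics = diag, ok = ok))
}

# Columnar CSV of the structural posterior draws (one row per draw).
write_draws_csv <- function(fit, path) {
  K <- length(fit$outcome_names); P <- length(fit$predictor_names)
  cols <- list(chain = fit$chain_id)
  for (k in seq_len(K)) {
    cols[[paste0("alpha.", fit$outcome_names[k])]] <- fit$draws$alpha[, k]
  }
  for (k in seq_len(K)) for (p in seq_len(P)) {
    cols[[paste0("beta.", fit$outcome_names[k], ".", fit$predictor_names[p])]] <-
      fit$draws$beta[, k, p]
  }
  for (k in seq_len(K)) {
    cols[[paste0("sigma_phylo.", fit$outcome_names[k])]] <- fit$draws$sigma_phylo[, k]
    cols[[paste0("tau.", fit$outcome_names[k])]] <- fit$draws$tau[, k]
  }
  if (K > 1) {
    for (k in seq_len(K - 1)) for (j in (k + 1):K) {
      cols[[paste0("Omega.", fit$outcome_names[k], ".", fit$outcome_names[j])]] <-
        fit$draws$Omega[, k, j]
    }
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Parameter-recovery report over synthetic replicates
#'
#' Simulates `n_replicates` studies from the configured truth preset, fits
#' each (complete-data fits at the configured MCMC profile), and reports, per
#' true-slope value across the outcome x socioecological-predictor cells:
#' 90% HPDI coverage, median bias, RMSE, the median probability of direction,
#' and the share of cells classified `"strong"`.
#'
#' @param config a [run_config()]; uses `n_replicates`, `truth_preset`,
#'   `profile`, `seed`, `n_societies`, `out_dir`.
#' @return (invisibly) list with `per_cell` (data.frame over replicates and
#'   cells) and `by_true_value` (aggregated data.frame).
#' @export
cmd_recover <- function(config) {
  logf <- start_run(config)
  prof <- mcmc_profile(config$profile)
  truth <- punish_truth(config$truth_preset)
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    seed_r <- config$seed + 1000L * r
    fx <- make_study_fixture(seed = seed_r, n = config$n_societies,
                             truth = truth, missing_rate = 0)
    C <- phylo_corr(fx$tree)
    spec <- model_spec(outcomes = truth$outcomes, predictors = truth$predictors,
                       s_alpha = config$s_alpha, s_beta = config$s_beta,
                       s_sd = config$s_sd, lkj_eta = config$lkj_eta,
                       use_society_effect = any(truth$tau > 0))
    fit <- fit_mcmc(spec, fx$design, fx$evidence$punishments, C,
                    chains = prof$chains, draws = prof$draws,
                    warmup = prof$warmup, seed = seed_r)
    summ <- summarize_effects(fit)
    summ <- summ[summ$predictor %in% socio_predictors(), ]
    summ$true <- mapply(function(o, p) truth$beta[o, p],
                        summ$outcome, summ$predictor)
    summ$covered <- summ$hpdi90_lo <= summ$true & summ$true <= summ$hpdi90_hi
    summ$replicate <- r
    rows[[r]] <- summ
    log_line(logf, sprintf("replicate %d/%d: coverage %.2f", r,
                           config$n_replicates, mean(summ$covered)))
  }
  per_cell <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_cell, per_cell$true), function(g) {
    data.frame(
      true = g$true[1], n_cells = nrow(g),
      coverage = mean(g$covered),
      median_bias = stats::median(g$median - g$true),
      rmse = sqrt(mean((g$median - g$true)^2)),
      median_pd = stats::median(g$pd),
      share_strong = mean(g$class == "strong")
    )
  }))
  rownames(agg) <- NULL
  utils::write.csv(per_cell, file.path(config$out_dir, "recovery_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(agg, file.path(config$out_dir, "recovery_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(agg, file.path(config$out_dir, "recovery_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(per_cell = per_cell, by_true_value = agg))
}
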