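#' Multiple imputation of socioecological predictors by chained equations
#'
#' Fills the missing cells of the six-predictor society table `m` times by
#' chained equations: each incomplete variable is regressed on the other five,
#' and missing entries are redrawn from the fitted conditional, sweeping over
#' variables several times before a completed table is kept. Binary variables
#' use bootstrap logistic draws (rows are resampled, a lightly ridge-penalised
#' logistic fit gives predicted probabilities, and the imputed value is a
#' Bernoulli draw); ordinal variables use predictive mean matching on a
#' bootstrap linear working model with a 5-donor pool, so imputed values are
#' always observed levels. Parameter uncertainty is carried by the bootstrap
#' resampling, giving proper between-imputation variability.
#'
#' @param socio data.frame with `society_id` plus the six predictor columns
#'   (see [socio_levels()]); missing cells coded `NA`.
#' @param m number of completed tables. Default 20.
#' @param seed integer seed; the whole set of tables is reproducible from it.
#' @param sweeps chained-equation sweeps per completed table. Default 10.
#' @return an object of class `imputed_set`: list with `m`, `tables` (list of
#'   completed data.frames), `seed`, `method_per_variable`, and
#'   `missing_mask` (logical matrix of originally missing cells).
#' @export
impute_chained <- function(socio, m = 20, seed = 1, sweeps = 10) {
  stopifnot(m >= 1, is.data.frame(socio))
  vars <- socio_predictors()
  if (!all(vars %in% names(socio))) {
    stop("socio table must contain columns: ", paste(vars, collapse = ", "),
         call. = FALSE)
  }
  lv <- socio_levels()
  dat <- as.matrix(socio[vars])
  storage.mode(dat) <- "double"
  miss <- is.na(dat)
  all_missing <- vars[colSums(!miss) == 0]
  if (length(all_missing) > 0) {
    stop("variable missing in every row: ", paste(all_missing, collapse = ", "),
         call. = FALSE)
  }
  methods <- vapply(vars, function(v) {
    if (lv[[v]]$type == "binary") "logreg.boot" else "pmm.boot"
  }, character(1))

  set.seed(seed %% .Machine$integer.max)
  incomplete <- vars[colSums(miss) > 0]
  tables <- vector("list", m)
  for (t in seq_len(m)) {
    work <- dat
    # initial fill: sample from observed marginals
    for (v in incomplete) {
      j <- match(v, vars)
      obs <- dat[!miss[, j], j]
      work[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
    }
    if (length(incomplete) > 0) {
      for (s in seq_len(sweeps)) {
        for (v in incomplete) {
          j <- match(v, vars)
          work[miss[, j], j] <- draw_conditional(
            y = dat[, j], X = work[, -j, drop = FALSE],
            miss_y = miss[, j], type = lv[[v]]$type
          )
        }
      }
    }
    out <- socio
    out[vars] <- as.data.frame(work)
    for (v in vars) {
      if (is.integer(socio[[v]])) out[[v]] <- as.integer(out[[v]])
    }
    tables[[t]] <- out
  }
  structure(
    list(m = m, tables = tables, seed = seed,
         method_per_variable = methods, missing_mask = miss),
    class = "imputed_set"
  )
}

# One conditional imputation draw for a single variable.
draw_conditional <- function(y, X, miss_y, type) {
  obs <- !miss_y
  n_obs <- sum(obs)
  idx <- sample.int(n_obs, replace = TRUE)
  Xo <- cbind(1, X[obs, , drop = FALSE])[idx, , drop = FALSE]
  yo <- y[obs][idx]
  Xm <- cbind(1, X[miss_y, , drop = FALSE])
  if (type == "binary") {
    beta <- ridge_logit(Xo, yo)
    p <- stats::plogis(drop(Xm %*% beta))
    stats::rbinom(nrow(Xm), 1, p)
  } else {
    # predictive mean matching on a linear working model, 5-donor pool
    fit <- stats::lm.fit(Xo, yo)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred_obs <- drop(cbind(1, X[obs, , drop = FALSE]) %*% beta)
    pred_mis <- drop(Xm %*% beta)
    y_obs <- y[obs]
    vapply(pred_mis, function(pm) {
      donors <- order(abs(pred_obs - pm))[seq_len(min(5L, n_obs))]
      y_obs[donors[sample.int(length(donors), 1)]]
    }, numeric(1))
  }
}

# IRLS logistic regression with a small ridge penalty on the slopes; the
# penalty keeps coefficients finite under (quasi-)separation while leaving
# near-deterministic conditionals near-deterministic.
ridge_logit <- function(X, y, lambda = 0.01, maxit = 50) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("<imputed_set> m = %d completed tables, %d originally missing cells, seed = %d\n",
              x$m, sum(x$missing_mask), x$seed))
  invisible(x)
}

#' Turn an imputed set into a fitting plan
#'
#' Decides how the `m` completed tables enter model fitting.
#' `"concatenate"` fits the model once per table with an equal share of the
#' requested posterior draws and concatenates the posteriors; `"mixture"`
#' fits a single model whose likelihood is, at every evaluation, the average
#' over tables of the complete-table likelihood. Both converge to the same
#' pooled posterior as m grows; concatenation is the default because it
#' parallelises trivially over tables.
#'
#' @param datasets an [impute_chained()] result.
#' @param strategy `"concatenate"` (default) or `"mixture"`.
#' @return an object of class `fit_plan` consumed by [fit_pooled()].
#' @export
pool_for_fitting <- function(datasets, strategy = c("concatenate", "mixture")) {
  stopifnot(inherits(datasets, "imputed_set"))
  strategy <- match.arg(strategy)
  structure(
    list(strategy = strategy, tables = datasets$tables, m = datasets$m,
         seed = datasets$seed),
    class = "fit_plan"
  )
}

#' Write an imputed set to disk
#'
#' One CSV per completed table plus a JSON manifest (seed, m, per-variable
#' methods, missing-cell count).
#'
#' @param datasets an [impute_chained()] result.
#' @param dir output directory (created if needed).
#' @export
write_imputed_set <- function(datasets, dir) {
  stopifnot(inherits(datasets, "imputed_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(datasets$m)) {
    utils::write.csv(datasets$tables[[t]],
                     file.path(dir, sprintf("imputed_%03d.csv", t)),
                     row.names = FALSE)
  }
  manifest <- list(
    m = datasets$m, seed = datasets$seed,
    method_per_variable = as.list(datasets$method_per_variable),
    n_missing_cells = sum(datasets$missing_mask)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
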