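#' Specify the multi-response phylogenetic logistic model
#'
#' Collects the outcome set, predictor set, and prior settings of the
#' multi-response, multi-predictor, multi-level phylogenetic logistic
#' regression. Priors are weakly regularising on the log-odds scale:
#' normal(0, `s_alpha`) intercepts, normal(0, `s_beta`) slopes,
#' half-normal(0, `s_sd`) random-effect SDs, and LKJ(`lkj_eta`) on the
#' correlation of the society-level effects.
#'
#' @param outcomes character vector of outcome names (default the four
#'   punishment types).
#' @param predictors character vector of design columns; any of the six
#'   socioecological predictors plus `"log_pages"`, `"pub_year"`,
#'   `"female_coauthor"`.
#' @param s_alpha,s_beta,s_sd prior scales (log-odds units). Defaults 2.5,
#'   2.5, 1.5.
#' @param lkj_eta LKJ concentration for the society-effect correlation.
#'   Default 2.
#' @param use_society_effect logical; `FALSE` drops the non-phylogenetic
#'   society-level effect (phylogeny-only variant). Default `TRUE`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcomes = punishment_types(),
                       predictors = c(socio_predictors(), "log_pages"),
                       s_alpha = 2.5, s_beta = 2.5, s_sd = 1.5,
                       lkj_eta = 2, use_society_effect = TRUE) {
  stopifnot(length(outcomes) >= 1, length(predictors) >= 1,
            s_alpha > 0, s_beta > 0, s_sd > 0, lkj_eta > 0)
  allowed <- c(socio_predictors(), "log_pages", "pub_year", "female_coauthor")
  unknown <- setdiff(predictors, allowed)
  if (length(unknown) > 0) {
    stop("unknown predictors: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(outcomes = outcomes, predictors = predictors,
         s_alpha = s_alpha, s_beta = s_beta, s_sd = s_sd, lkj_eta = lkj_eta,
         use_society_effect = use_society_effect),
    class = "model_spec"
  )
}

#' Build the design matrix for model fitting
#'
#' Assembles the S x P predictor matrix in a fixed row order (the phylogeny's
#' taxa order). Binary predictors enter as 0/1 (presence / stratified = 1);
#' ordinal predictors enter as z-scored integer ranks (monotonic-linear
#' coding); `log_pages` is the z-scored log of document page count;
#' `pub_year` is z-scored publication year; `female_coauthor` is 0/1.
#'
#' @param socio completed (no `NA`) socioecology data.frame with `society_id`,
#'   or `NULL` if no socioecological predictors are requested.
#' @param docs document metadata data.frame with `society_id` (needed for the
#'   meta-ethnographic covariates).
#' @param spec a [model_spec()].
#' @param taxa_order character vector fixing the row order (defaults to
#'   `socio$society_id` order).
#' @return matrix with `taxa_order` rownames, `spec$predictors` columns, and a
#'   `transform_log` attribute recording each column's transformation.
#' @export
build_design <- function(socio, docs, spec, taxa_order = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  lv <- socio_levels()
  src <- if (!is.null(socio)) socio else docs
  if (is.null(taxa_order)) taxa_order <- src$society_id

  need_socio <- intersect(spec$predictors, socio_predictors())
  if (length(need_socio) > 0) {
    if (is.null(socio)) stop("socio table required for predictors: ",
                             paste(need_socio, collapse = ", "), call. = FALSE)
    if (anyNA(socio[need_socio])) {
      stop("design requires a completed table; impute missing cells first",
           call. = FALSE)
    }
  }

  pick_rows <- function(df) {
    idx <- match(taxa_order, df$society_id)
    if (anyNA(idx)) {
      stop("societies not found in table: ",
           paste(taxa_order[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    df[idx, , drop = FALSE]
  }
  socio_o <- if (!is.null(socio)) pick_rows(socio) else NULL
  docs_o <- if (!is.null(docs)) pick_rows(docs) else NULL

  n <- length(taxa_order)
  Xcols <- vector("list", length(spec$predictors))
  tlog <- vector("list", length(spec$predictors))
  names(Xcols) <- names(tlog) <- spec$predictors
  for (v in spec$predictors) {
    if (v %in% socio_predictors()) {
      raw <- socio_o[[v]]
      if (lv[[v]]$type == "binary") {
        Xcols[[v]] <- as.numeric(raw)
        tlog[[v]] <- list(type = "binary")
      } else {
        z <- zscore_col(as.numeric(raw), v)
        Xcols[[v]] <- z$x
        tlog[[v]] <- list(type = "ordinal_z", mean = z$mean, sd = z$sd)
      }
    } else if (v == "log_pages") {
      z <- zscore_col(log(as.numeric(docs_o$page_count)), v)
      Xcols[[v]] <- z$x
      tlog[[v]] <- list(type = "log_z", mean = z$mean, sd = z$sd)
    } else if (v == "pub_year") {
      z <- zscore_col(as.numeric(docs_o$pub_year), v)
      Xcols[[v]] <- z$x
      tlog[[v]] <- list(type = "z", mean = z$mean, sd = z$sd)
    } else if (v == "female_coauthor") {
      Xcols[[v]] <- as.numeric(docs_o$female_coauthor)
      tlog[[v]] <- list(type = "binary")
    }
    if (stats::sd(Xcols[[v]]) == 0) {
      stop("degenerate (constant) design column: ", v, call. = FALSE)
    }
  }
  X <- do.call(cbind, Xcols)
  dimnames(X) <- list(taxa_order, spec$predictors)
  attr(X, "transform_log") <- tlog
  X
}

zscore_col <- function(x, name) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) {
    stop("degenerate (constant) design column: ", name, call. = FALSE)
  }
  list(x = (x - mean(x)) / s, mean = mean(x), sd = s)
}
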