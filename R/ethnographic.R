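#' @keywords internal
#' @useDynLib punishr
"_PACKAGE"

# Canonical variable names used throughout the package.

#' The five norm-violation domains, in canonical order
#' @return character vector.
#' @export
violation_domains <- function() {
  c("adultery", "religious", "food", "rape", "war_cowardice")
}

#' The four punishment types, in canonical order
#' @return character vector.
#' @export
punishment_types <- function() {
  c("reputational", "material", "physical", "execution")
}

#' The six socioecological predictor names, in canonical order
#' @return character vector.
#' @export
socio_predictors <- function() {
  c("external_trade", "animal_husbandry", "dependence_hunting",
    "food_storage", "community_size", "social_stratification")
}

#' The twenty domain-by-punishment cell names (`domain.type`)
#' @return character vector.
#' @export
cell_names <- function() {
  as.vector(t(outer(violation_domains(), punishment_types(), paste, sep = ".")))
}

#' Declared level sets for the socioecological predictors
#'
#' Binary predictors are coded 0/1 (presence = 1; stratified = 1). The two
#' dependence measures are ordinal intensity classes 0-4 and community size is
#' an ordinal bin 1-7. Missing cells are coded `NA`, never zero.
#'
#' @return named list; each element has `type` ("binary" or "ordinal") and the
#'   admissible `levels`.
#' @export
socio_levels <- function() {
  list(
    external_trade        = list(type = "binary",  levels = 0:1),
    animal_husbandry      = list(type = "ordinal", levels = 0:4),
    dependence_hunting    = list(type = "ordinal", levels = 0:4),
    food_storage          = list(type = "binary",  levels = 0:1),
    community_size        = list(type = "ordinal", levels = 1:7),
    social_stratification = list(type = "binary",  levels = 0:1)
  )
}

#' Construct a validated evidence matrix
#'
#' Holds the per-society binary evidence flags: 5 norm-violation domains,
#' 4 punishment types, and the 20 domain-by-punishment cells. Two structural
#' invariants are enforced: a positive cell implies a positive violation flag
#' for its domain (every punishment observation documents its violation), and
#' a punishment flag is positive exactly when at least one of its 5 cells is.
#'
#' @param society_id character vector of unique society labels.
#' @param violations S x 5 binary matrix, columns [violation_domains()].
#' @param punishments S x 4 binary matrix, columns [punishment_types()].
#' @param cells S x 20 binary matrix, columns `domain.punishment`.
#' @return an object of class `evidence_matrix`.
#' @export
evidence_matrix <- function(society_id, violations, punishments, cells) {
  society_id <- as.character(society_id)
  if (anyDuplicated(society_id)) {
    stop("duplicate society_id: ",
         paste(unique(society_id[duplicated(society_id)]), collapse = ", "),
         call. = FALSE)
  }
  violations <- as_flag_matrix(violations, violation_domains(), society_id)
  punishments <- as_flag_matrix(punishments, punishment_types(), society_id)
  cells <- as_flag_matrix(cells, cell_names(), society_id)

  for (d in violation_domains()) {
    dcells <- cells[, paste(d, punishment_types(), sep = "."), drop = FALSE]
    bad <- which(rowSums(dcells) > 0 & violations[, d] == 0)
    if (length(bad) > 0) {
      stop(sprintf(
        "containment violated: cell evidence without violation evidence for domain '%s' in rows %s",
        d, paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  for (p in punishment_types()) {
    pcells <- cells[, paste(violation_domains(), p, sep = "."), drop = FALSE]
    derived <- as.integer(rowSums(pcells) > 0)
    bad <- which(derived != punishments[, p])
    if (length(bad) > 0) {
      stop(sprintf(
        "punishment flag '%s' inconsistent with its cells in rows %s",
        p, paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  structure(
    list(society_id = society_id, violations = violations,
         punishments = punishments, cells = cells),
    class = "evidence_matrix"
  )
}

as_flag_matrix <- function(x, cols, society_id) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- cols
  if (!setequal(colnames(x), cols)) {
    stop("expected columns ", paste(cols, collapse = ", "),
         "; got ", paste(colnames(x), collapse = ", "), call. = FALSE)
  }
  x <- x[, cols, drop = FALSE]
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("non-binary value in flag matrix (flags must be 0/1)", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  rownames(x) <- society_id
  x
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat(sprintf(
    "<evidence_matrix> %d societies, %d violation domains, %d punishment types\n",
    length(x$society_id), ncol(x$violations), ncol(x$punishments)
  ))
  invisible(x)
}

#' Read a culture-document coding table
#'
#' Parses a CSV with one row per culture-document: document metadata
#' (`society_id`, `region`, `subsistence_class`, `page_count`, `pub_year`,
#' `female_coauthor`), the 9 evidence flags (`v_<domain>`, `p_<type>`), the 20
#' `c_<domain>_<type>` cells, and the six socioecological predictors (which may
#' be `NA`). Optional annotation columns (`evidence_against`, `subcode`) are
#' carried through but ignored by every computation, matching the coding
#' scheme's treatment of sub-codes.
#'
#' @param path CSV file path.
#' @param na string representing missing values. Default `"NA"`.
#' @return list with elements `docs` (data.frame of document metadata),
#'   `evidence` ([evidence_matrix]), and `socio` (data.frame of predictors
#'   with explicit `NA` for missing cells).
#' @export
read_coding_table <- function(path, na = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, na.strings = na, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no rows in coding table: ", path, call. = FALSE)

  doc_cols <- c("society_id", "region", "subsistence_class", "page_count",
                "pub_year", "female_coauthor")
  v_cols <- paste0("v_", violation_domains())
  p_cols <- paste0("p_", punishment_types())
  c_cols <- paste0("c_", gsub(".", "_", cell_names(), fixed = TRUE))
  s_cols <- socio_predictors()
  optional <- c("evidence_against", "subcode")

  known <- c(doc_cols, v_cols, p_cols, c_cols, s_cols, optional)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown columns: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  needed <- setdiff(known, optional)
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0) {
    stop("missing columns: ", paste(absent, collapse = ", "), call. = FALSE)
  }

  for (col in c(v_cols, p_cols, c_cols)) {
    vals <- raw[[col]]
    bad <- which(is.na(vals) | !(vals %in% c(0, 1)))
    if (length(bad) > 0) {
      stop(sprintf("non-binary value in flag column '%s', rows %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (any(raw$page_count < 1 | is.na(raw$page_count))) {
    stop("page_count must be a positive integer in every row", call. = FALSE)
  }

  docs <- raw[doc_cols]
  docs$female_coauthor <- as.integer(docs$female_coauthor)

  violations <- as.matrix(raw[v_cols]); colnames(violations) <- violation_domains()
  punishments <- as.matrix(raw[p_cols]); colnames(punishments) <- punishment_types()
  cells <- as.matrix(raw[c_cols]); colnames(cells) <- cell_names()
  ev <- evidence_matrix(raw$society_id, violations, punishments, cells)

  socio <- raw[s_cols]
  lv <- socio_levels()
  for (v in s_cols) {
    out_of_set <- which(!is.na(socio[[v]]) & !(socio[[v]] %in% lv[[v]]$levels))
    if (length(out_of_set) > 0) {
      stop(sprintf("predictor '%s' outside declared level set in rows %s",
                   v, paste(out_of_set, collapse = ", ")), call. = FALSE)
    }
  }
  socio <- data.frame(society_id = raw$society_id, socio,
                      stringsAsFactors = FALSE, check.names = FALSE)
  n_missing <- sum(is.na(socio[s_cols]))
  message(sprintf("read %d culture-documents; %d missing predictor cells",
                  nrow(raw), n_missing))
  list(docs = docs, evidence = ev, socio = socio)
}

#' Prevalence of an evidence flag
#'
#' Fraction of societies whose flag is 1. `variable` may be a violation
#' domain, a punishment type, or one of the aggregates `"any_violation"` /
#' `"any_punishment"`.
#'
#' @param em an [evidence_matrix].
#' @param variable flag name.
#' @return a fraction in `[0, 1]`.
#' @export
prevalence <- function(em, variable) {
  stopifnot(inherits(em, "evidence_matrix"))
  if (variable %in% violation_domains()) {
    return(mean(em$violations[, variable]))
  }
  if (variable %in% punishment_types()) {
    return(mean(em$punishments[, variable]))
  }
  if (variable == "any_violation") return(mean(rowSums(em$violations) > 0))
  if (variable == "any_punishment") return(mean(rowSums(em$punishments) > 0))
  stop("unknown variable: ", variable, call. = FALSE)
}

#' Violation / punishment co-occurrence statistics
#'
#' For each violation domain, compares the violation flag with the OR of its
#' four punishment cells ("any punishment for this domain"): the phi
#' coefficient (Pearson correlation of the two 0/1 vectors) and the Jaccard
#' index of their positive sets. A zero-variance vector leaves the correlation
#' undefined (`NA`, flagged); the Jaccard index is still computed.
#'
#' @param em an [evidence_matrix].
#' @return list with `per_domain` (data.frame: domain, phi, jaccard,
#'   phi_defined), `mean_phi`, `mean_jaccard`, `min_phi`, `max_phi` (the
#'   means are unweighted over domains with a defined value).
#' @export
cooccurrence_stats <- function(em) {
  stopifnot(inherits(em, "evidence_matrix"))
  if (length(em$society_id) < 2) stop("need at least 2 societies", call. = FALSE)
  doms <- violation_domains()
  phi <- jac <- numeric(length(doms))
  defined <- logical(length(doms))
  for (i in seq_along(doms)) {
    v <- em$violations[, doms[i]]
    anyp <- as.integer(rowSums(
      em$cells[, paste(doms[i], punishment_types(), sep = "."), drop = FALSE]
    ) > 0)
    defined[i] <- stats::sd(v) > 0 && stats::sd(anyp) > 0
    phi[i] <- if (defined[i]) stats::cor(v, anyp) else NA_real_
    uni <- sum(v == 1 | anyp == 1)
    jac[i] <- if (uni > 0) sum(v == 1 & anyp == 1) / uni else NA_real_
  }
  list(
    per_domain = data.frame(domain = doms, phi = phi, jaccard = jac,
                            phi_defined = defined),
    mean_phi = mean(phi, na.rm = TRUE),
    mean_jaccard = mean(jac, na.rm = TRUE),
    min_phi = if (any(defined)) min(phi, na.rm = TRUE) else NA_real_,
    max_phi = if (any(defined)) max(phi, na.rm = TRUE) else NA_real_
  )
}

#' Cross-tabulation of evidence counts
#'
#' Counts, for each violation domain and punishment type, the societies whose
#' domain-by-punishment cell flag is 1 (the mosaic-plot table).
#'
#' @param em an [evidence_matrix].
#' @return a 5 x 4 integer matrix (domains x punishment types).
#' @export
crosstab_counts <- function(em) {
  stopifnot(inherits(em, "evidence_matrix"))
  counts <- matrix(0L, nrow = 5, ncol = 4,
                   dimnames = list(violation_domains(), punishment_types()))
  for (d in violation_domains()) {
    for (p in punishment_types()) {
      counts[d, p] <- sum(em$cells[, paste(d, p, sep = ".")])
    }
  }
  counts
}
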