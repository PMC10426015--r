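#' Parse a Newick string into a validated phylogeny
#'
#' Reads a rooted tree in Newick format and returns an [ape::phylo] object
#' after validation: leaf labels must be unique, branch lengths must be
#' non-negative, and unary internal nodes are collapsed (their branch lengths
#' summed). Edges without a stated length receive `default_length`, the usual
#' supertree convention.
#'
#' @param text a single Newick string, terminated by `;`.
#' @param default_length branch length substituted where the Newick string
#'   states none. Default 1.
#' @return an object of class `phylo` with `tip.label` and `edge.length`.
#' @export
parse_newick <- function(text, default_length = 1) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse failed: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse failed: no tree found in string", call. = FALSE)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  tree <- ape::collapse.singles(tree)
  validate_phylogeny(tree)
  tree
}

# Cheap structural scan so malformed strings fail with a character offset
# instead of an opaque ape error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i), call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf(
      "malformed Newick: %d unclosed '(' (string ends at character %d)",
      depth, length(chars)
    ), call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop(sprintf(
      "malformed Newick: missing terminating ';' at character %d", length(chars)
    ), call. = FALSE)
  }
  invisible(TRUE)
}

validate_phylogeny <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  invisible(tree)
}

#' Write a phylogeny to a Newick string
#'
#' @param tree a `phylo` object.
#' @return a Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Prune a phylogeny to a set of taxa
#'
#' Removes all leaves not in `keep` and collapses the resulting unary internal
#' nodes, summing branch lengths, so that patristic distances among the kept
#' taxa are unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of leaf labels to retain (must all be present).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2) stop("need at least 2 taxa to keep", call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  pruned <- ape::keep.tip(tree, keep)
  validate_phylogeny(pruned)
  pruned
}

#' Brownian-motion variance-covariance matrix of a phylogeny
#'
#' Under a Brownian model of trait change along the tree, the covariance of
#' two leaves is the total branch length shared by their root-to-leaf paths,
#' i.e. the depth of their most recent common ancestor; the variance of a leaf
#' is its root-to-leaf depth.
#'
#' @param tree a `phylo` object.
#' @return a symmetric matrix with row/column names equal to `tree$tip.label`.
#' @export
vcv_from_tree <- function(tree) {
  validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Standardise a phylogenetic covariance matrix to a correlation matrix
#'
#' Divides each row/column by the square root of its own diagonal entry
#' (its root-to-leaf depth), so the result has unit diagonal and the
#' phylogenetic variance parameter of the regression model is on a common
#' scale. Each leaf is scaled by its own depth, so non-ultrametric trees are
#' permitted. If the smallest eigenvalue falls below `psd_tol`, a diagonal
#' jitter is added (and recorded) to restore positive definiteness.
#'
#' @param V symmetric covariance matrix with strictly positive diagonal.
#' @param jitter diagonal jitter used for PSD repair. Default 1e-6.
#' @param psd_tol smallest admissible eigenvalue before repair. Default 1e-8.
#' @return a correlation matrix (class `phylo_corr`) with attributes
#'   `taxa` (label order) and `jitter` (0 if no repair was needed).
#' @export
standardize_vcv <- function(V, jitter = 1e-6, psd_tol = 1e-8) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  d <- diag(V)
  if (any(d <= 0)) {
    bad <- rownames(V)[d <= 0]
    if (is.null(bad)) bad <- which(d <= 0)
    stop("zero or negative diagonal for taxa: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (max(abs(V - t(V))) > 1e-12 * max(abs(V), 1)) {
    stop("covariance matrix is not symmetric", call. = FALSE)
  }
  s <- 1 / sqrt(d)
  C <- V * tcrossprod(s)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  applied <- 0
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < psd_tol) {
    applied <- jitter
    diag(C) <- diag(C) + jitter
    message(sprintf(
      "standardize_vcv: smallest eigenvalue %.3g below tolerance; added diagonal jitter %g",
      ev_min, jitter
    ))
  }
  structure(C,
    taxa = rownames(V),
    jitter = applied,
    class = c("phylo_corr", "matrix", "array")
  )
}

#' Phylogenetic correlation matrix from a tree
#'
#' Convenience wrapper: [vcv_from_tree()] followed by [standardize_vcv()].
#' The source tree is kept as an attribute so downstream model code can use
#' the exact sparse square root of the correlation (see [phylo_factor()])
#' instead of a dense Cholesky factor.
#'
#' @inheritParams vcv_from_tree
#' @inheritParams standardize_vcv
#' @return a `phylo_corr` correlation matrix in `tree$tip.label` order.
#' @export
phylo_corr <- function(tree, jitter = 1e-6, psd_tol = 1e-8) {
  C <- standardize_vcv(vcv_from_tree(tree), jitter = jitter, psd_tol = psd_tol)
  if (attr(C, "jitter") == 0) attr(C, "tree") <- tree
  C
}

#' Sparse square root of the standardised tree covariance
#'
#' Builds the leaf-by-edge incidence factor `B` with
#' `B[s, e] = sqrt(length_e) / sqrt(depth_s)` for every edge `e` on the
#' root-to-leaf path of `s`, so that `B %*% t(B)` equals the standardised
#' Brownian correlation matrix exactly. Each row has one entry per ancestor
#' edge (O(log S) for Yule-like trees), which makes latent phylogenetic
#' effects `B %*% z` with `z ~ N(0, I)` far cheaper than a dense Cholesky
#' product of the same distribution.
#'
#' @param tree a `phylo` object.
#' @param taxa_order row order (defaults to `tree$tip.label`).
#' @return a sparse `dgCMatrix` with `taxa_order` rownames.
#' @export
phylo_factor <- function(tree, taxa_order = tree$tip.label) {
  validate_phylogeny(tree)
  S <- length(tree$tip.label)
  depths <- node_depths(tree)
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  # tip sets under each edge's child, by postorder accumulation
  tips_under <- vector("list", max(tree$edge))
  for (tip in seq_len(S)) tips_under[[tip]] <- tip
  ord <- order(-depths[child])  # deeper children first, so kids are ready
  for (e in ord) {
    if (child[e] > S) {
      kids <- which(parent == child[e])
      tips_under[[child[e]]] <- unlist(tips_under[child[kids]])
    }
  }
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (e in seq_along(child)) {
    tips <- tips_under[[child[e]]]
    rows <- c(rows, tips)
    cols <- c(cols, rep.int(e, length(tips)))
    vals <- c(vals, rep.int(sqrt(tree$edge.length[e]), length(tips)))
  }
  vals <- vals / sqrt(depths[rows])
  B <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(S, nrow(tree$edge)),
                            dimnames = list(tree$tip.label, NULL))
  B[taxa_order, , drop = FALSE]
}

node_depths <- function(tree) {
  n_node <- max(tree$edge)
  depths <- numeric(n_node)
  # edges in preorder: repeatedly sweep until all children assigned
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  remaining <- seq_along(child)
  root <- setdiff(parent, child)[1]
  done <- rep(FALSE, n_node)
  done[root] <- TRUE
  while (length(remaining) > 0) {
    ready <- remaining[done[parent[remaining]]]
    if (length(ready) == 0) stop("malformed tree edges", call. = FALSE)
    depths[child[ready]] <- depths[parent[ready]] + tree$edge.length[ready]
    done[child[ready]] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  depths
}

#' Write a correlation matrix as CSV with a taxa header
#'
#' @param C matrix with row/column names.
#' @param path output file.
#' @export
write_corr_csv <- function(C, path) {
  df <- data.frame(taxon = rownames(C), as.data.frame(unclass(C)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
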