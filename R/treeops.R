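#' Read a rooted Newick tree with branch lengths
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must be a
#' single rooted tree, every edge must carry a finite nonnegative branch
#' length, and tip labels must be unique. Violations raise classed errors
#' (`glandcov_parse_error`, `glandcov_branchlength_error`,
#' `glandcov_duplicate_label_error`) rather than being repaired silently.
#'
#' @param path Path to a Newick file containing one tree.
#' @return An object of class `phylo` (see \pkg{ape}).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop_glandcov("parse", "Newick file not found: ", path)
  }
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    stop_glandcov("parse", "could not parse '", path, "' as a Newick tree")
  }
  if (inherits(tr, "multiPhylo")) {
    stop_glandcov("parse", "'", path, "' contains more than one tree")
  }
  validate_tree(tr)
  tr
}

#' @rdname read_newick
#' @param text Newick string (alternative to a file).
#' @export
read_newick_text <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || inherits(tr, "multiPhylo")) {
    stop_glandcov("parse", "could not parse text as a single Newick tree")
  }
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) {
    stop_glandcov("parse", "not a phylogenetic tree")
  }
  if (length(tr$tip.label) < 2) {
    stop_glandcov("parse", "tree must have at least 2 tips")
  }
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop_glandcov("duplicate_label", "duplicate tip labels: ",
                  paste(dup, collapse = ", "))
  }
  if (is.null(tr$edge.length)) {
    stop_glandcov("branchlength", "tree has no branch lengths")
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0)) {
    stop_glandcov("branchlength",
                  "all branch lengths must be finite and nonnegative")
  }
  # the Newick root node is taken as the root; trees with a basal
  # polytomy (e.g. a star phylogeny) are rooted at that polytomy
  invisible(tr)
}

#' Prune a tree to a set of tips
#'
#' Restricts the tree to `keep`, collapsing degree-2 internal nodes and
#' summing their branch lengths, so all pairwise path lengths between
#' retained tips are preserved exactly.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` tree.
#' @export
prune_to <- function(tree, keep) {
  validate_tree(tree)
  keep <- as.character(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop_glandcov("missing_taxon", "taxa not in tree: ",
                  paste(missing, collapse = ", "))
  }
  if (length(keep) < 2) {
    stop_glandcov("prune", "need at least 2 tips to keep")
  }
  ape::keep.tip(tree, keep)
}

#' Brownian-motion trait covariance of a tree
#'
#' Under Brownian motion the expected covariance of a trait between tips i
#' and j is the shared branch length from the root to their most recent
#' common ancestor; the variance at tip i is its root-to-tip distance.
#'
#' @param tree A `phylo` object.
#' @param order Optional character vector: a permutation of the tip labels
#'   giving the row/column order of the returned matrix. Defaults to the
#'   tree's own tip order.
#' @return An n x n symmetric matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree, order = NULL) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(order)) {
    order <- as.character(order)
    if (length(order) != length(tree$tip.label) ||
        !setequal(order, tree$tip.label) || anyDuplicated(order)) {
      stop_glandcov("alignment",
                    "'order' must be a permutation of the tree's tip labels")
    }
    C <- C[order, order, drop = FALSE]
  }
  C
}

#' Symmetric whitening matrix of an SPD covariance
#'
#' Computes `E = U %*% diag(1/sqrt(lambda)) %*% t(U)` from the symmetric
#' eigendecomposition `C = U diag(lambda) t(U)`, so that `E C E = I` and
#' `E` is itself symmetric (the inverse principal square root). This is the
#' phylogenetic transform applied to trait matrices before PLS/regression.
#'
#' @param C Symmetric positive-definite matrix.
#' @param tol Relative eigenvalue floor: eigenvalues below
#'   `tol * max(lambda)` raise a conditioning error instead of being
#'   regularized silently.
#' @return Symmetric matrix `E` with the same dimnames as `C`.
#' @export
whitener <- function(C, tol = 1e-12) {
  C <- as.matrix(C)
  if (!isSymmetric(C, tol = 1e-8)) {
    stop_glandcov("conditioning", "C must be symmetric")
  }
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- eg$values
  if (any(lam <= tol * max(lam))) {
    stop_glandcov("conditioning",
                  "covariance is numerically singular (min eigenvalue ",
                  format(min(lam)), " below floor)")
  }
  E <- eg$vectors %*% (t(eg$vectors) / sqrt(lam))
  dimnames(E) <- dimnames(C)
  E
}

#' Phylogenetic (GLS) mean of trait columns
#'
#' The generalized-least-squares estimate of the root value of each trait,
#' `a = (1' C^-1 1)^-1 1' C^-1 Y`, which is the correct centering under
#' phylogenetic dependence; reduces to the arithmetic column mean when
#' `C` is proportional to the identity.
#'
#' @param C n x n SPD covariance among species.
#' @param Y n x q numeric matrix (or vector) of traits, rows aligned to `C`.
#' @return Numeric vector of length q.
#' @export
gls_mean <- function(C, Y) {
  Y <- as.matrix(Y)
  C <- as.matrix(C)
  if (nrow(Y) != nrow(C)) {
    stop_glandcov("alignment", "nrow(Y) must equal nrow(C)")
  }
  one <- rep(1, nrow(C))
  s <- tryCatch(solve(C, cbind(one, Y)), error = function(e)
    stop_glandcov("conditioning", "C is singular"))
  out <- drop(crossprod(one, s[, -1, drop = FALSE]) / sum(s[, 1]))
  names(out) <- colnames(Y)
  out
}

# classed fail-fast errors used across the package
stop_glandcov <- function(class, ...) {
  stop(errorCondition(paste0(...),
                      class = c(paste0("glandcov_", class, "_error"),
                                "glandcov_error", "error", "condition")))
}
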