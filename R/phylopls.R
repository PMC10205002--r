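#' Phylogenetic two-block partial least squares
#'
#' Quantifies covariation between two trait blocks measured on the tips of
#' a phylogeny, after removing the expected Brownian-motion dependence
#' among species. Both blocks are centered on their phylogenetic (GLS)
#' mean and premultiplied by the inverse principal square root of the
#' Brownian covariance `C`; the first singular pair of the cross-block
#' covariance gives one axis per block, and `r_PLS` is the absolute
#' correlation of the two score vectors. Significance comes from
#' permuting the rows of the transformed second block (holding the
#' phylogenetic transform fixed), so the permutation breaks the
#' cross-block association but not the phylogenetic structure.
#'
#' Works for high-dimensional blocks (more variables than species): the
#' only cross-variable object formed is the p1 x p2 cross-covariance.
#'
#' @param X1,X2 Species x variables numeric matrices with species row
#'   names matching the tree tips.
#' @param tree `phylo` object covering exactly the species of the blocks.
#' @param n_perm Number of permutations for the null distribution.
#' @param seed Integer seed governing the permutation stream.
#' @return Object of class `phylo_pls` with elements `r_pls`, `p_value`,
#'   `left_loadings`, `right_loadings`, `left_scores`, `right_scores`,
#'   `singular_values`, `n_perm`, `seed`, `perm_r`.
#' @export
phylo_pls <- function(X1, X2, tree, n_perm = 999L, seed = 1L) {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop_glandcov("pls", "n_perm must be >= 1")
  al <- align_blocks(list(X1, X2), tree)
  X1 <- al$mats[[1]]; X2 <- al$mats[[2]]; tree <- al$tree
  n <- nrow(X1)
  if (n < 4L) stop_glandcov("pls", "need at least 4 species")

  C <- bm_covariance(tree, order = rownames(X1))
  E <- whitener(C)
  X1t <- E %*% sweep(X1, 2L, gls_mean(C, X1), "-")
  X2t <- E %*% sweep(X2, 2L, gls_mean(C, X2), "-")
  if (all(abs(X1t) < 1e-12) || all(abs(X2t) < 1e-12)) {
    stop_glandcov("pls", "a block has zero variance after transformation")
  }

  obs <- pls_first_axis(X1t, X2t)

  set.seed(as.integer(seed))
  perm_r <- vapply(seq_len(n_perm), function(i) {
    pls_first_axis(X1t, X2t[sample(n), , drop = FALSE], scores = FALSE)$r
  }, numeric(1))
  p <- (1 + sum(perm_r >= obs$r - 1e-12)) / (n_perm + 1)

  structure(list(
    r_pls = obs$r, p_value = p,
    left_loadings = obs$u, right_loadings = obs$v,
    left_scores = obs$s1, right_scores = obs$s2,
    singular_values = obs$d,
    n_perm = n_perm, seed = as.integer(seed), perm_r = perm_r,
    species = rownames(X1)
  ), class = "phylo_pls")
}

# first singular pair of the cross-block covariance of (already
# transformed, centered) blocks; r is |cor| of the paired scores
pls_first_axis <- function(X1t, X2t, scores = TRUE) {
  n <- nrow(X1t)
  R12 <- crossprod(X1t, X2t) / (n - 1)
  sv <- svd(R12, nu = 1L, nv = 1L)
  u <- sv$u[, 1L]
  v <- sv$v[, 1L]
  s1 <- drop(X1t %*% u)
  s2 <- drop(X2t %*% v)
  r <- stats::cor(s1, s2)
  if (is.na(r)) r <- 0
  if (r < 0) {          # sign convention: scores positively associated
    v <- -v
    s2 <- -s2
    r <- -r
  }
  if (!scores) return(list(r = r))
  names(u) <- colnames(X1t)
  names(v) <- colnames(X2t)
  names(s1) <- names(s2) <- rownames(X1t)
  list(r = r, u = u, v = v, s1 = s1, s2 = s2, d = sv$d)
}

#' Map PLS loadings back to original (compositional) variables
#'
#' Loadings are estimated in the transformed space of CLR variables; for
#' display the loading vector is read as a direction on the CLR scale and
#' optionally mapped through [clr_inverse()] to a composition.
#'
#' @param loadings Numeric loading vector on CLR variables.
#' @param as_composition If `TRUE`, return `clr_inverse` of the loading
#'   direction (a composition); otherwise the CLR-scale vector unchanged.
#' @return Numeric vector.
#' @export
backmap_loadings <- function(loadings, as_composition = FALSE) {
  if (!as_composition) return(loadings)
  drop(clr_inverse(matrix(loadings, nrow = 1L)))
}

#' @export
print.phylo_pls <- function(x, ...) {
  cat("Phylogenetic two-block PLS\n")
  cat(sprintf("  species: %d   block dims: %d x %d\n",
              length(x$species), length(x$left_loadings),
              length(x$right_loadings)))
  cat(sprintf("  r_PLS = %.4f   P = %.4g   (%d permutations)\n",
              x$r_pls, x$p_value, x$n_perm))
  invisible(x)
}

# align a list of species x variable matrices to the tree's tip order;
# exact, case-sensitive label matching, mismatches are fatal
align_blocks <- function(mats, tree) {
  validate_tree(tree)
  tips <- tree$tip.label
  mats <- lapply(mats, function(M) {
    M <- as.matrix(M)
    if (is.null(rownames(M))) {
      if (nrow(M) != length(tips)) {
        stop_glandcov("alignment",
                      "unlabeled matrix rows do not match number of tips")
      }
      rownames(M) <- tips
      return(M)
    }
    extra <- setdiff(rownames(M), tips)
    miss <- setdiff(tips, rownames(M))
    if (length(extra) || length(miss)) {
      stop_glandcov("alignment", "species mismatch with tree",
                    if (length(miss)) paste0("; missing from data: ",
                                             paste(miss, collapse = ", ")),
                    if (length(extra)) paste0("; not in tree: ",
                                              paste(extra, collapse = ", ")))
    }
    M[tips, , drop = FALSE]
  })
  list(mats = mats, tree = tree)
}
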