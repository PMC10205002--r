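# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# shared root-to-MRCA path length for every tip pair, by explicit edge
# enumeration: walk root->tip paths and sum the lengths of common edges
oracle_bm_covariance <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  # parent lookup: for each node, (parent, edge length)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  path_edges <- function(tip) {
    e <- integer(0)
    node <- tip
    while (node != root) {
      e <- c(e, node)       # identify each edge by its child node
      node <- parent[node]
    }
    e
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(elen[shared])
    }
  }
  C
}

# O(n * w) exhaustive scan peak detector: strict local maxima over a
# truncated centered window, endpoints never peaks, 10%-of-tallest filter
oracle_detect_peaks <- function(p, window = 3L, rel_height = 0.10) {
  n <- length(p)
  half <- (window - 1L) %/% 2L
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    ok <- TRUE
    for (j in max(1L, i - half):min(n, i + half)) {
      if (j != i && p[j] >= p[i]) { ok <- FALSE; break }
    }
    if (ok) cand <- c(cand, i)
  }
  if (!length(cand)) return(integer(0))
  cand[p[cand] >= rel_height * max(p[cand])]
}

# plain (non-phylogenetic) two-block PLS first-axis correlation:
# arithmetic centering, SVD of the cross-covariance
oracle_plain_pls_r <- function(X1, X2) {
  X1 <- scale(X1, center = TRUE, scale = FALSE)
  X2 <- scale(X2, center = TRUE, scale = FALSE)
  sv <- svd(crossprod(X1, X2) / (nrow(X1) - 1), nu = 1, nv = 1)
  abs(cor(X1 %*% sv$u, X2 %*% sv$v))
}

# star phylogeny with unit branch lengths (C = I)
star_tree <- function(n, len = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

random_spd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.5
}
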