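test_that("Newick reading preserves topology, labels and depths", {
  tr <- read_newick_text("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)[seq_len(3)]
  expect_equal(unname(depths), c(2, 2, 2))

  tr2 <- read_newick_text("(A:1,B:1);")
  expect_length(tr2$tip.label, 2)

  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tmp)
  expect_equal(read_newick(tmp)$tip.label, tr$tip.label)
})

test_that("invalid trees raise named errors", {
  expect_error(read_newick_text("((A:1,A:1):1,C:2);"),
               class = "glandcov_duplicate_label_error")
  expect_error(read_newick_text("((A,B),C);"),
               class = "glandcov_branchlength_error")
  expect_error(read_newick("/nonexistent/file.nwk"),
               class = "glandcov_parse_error")
})

test_that("pruning preserves pairwise path lengths", {
  tr <- read_newick_text("((A:1,B:1):1,C:2);")
  pr <- prune_to(tr, c("A", "C"))
  expect_equal(unname(ape::cophenetic.phylo(pr)["A", "C"]), 4)

  # identity case: keeping all tips leaves the distance matrix unchanged
  full <- ape::cophenetic.phylo(tr)
  same <- ape::cophenetic.phylo(prune_to(tr, tr$tip.label))
  expect_equal(same[rownames(full), colnames(full)], full)

  # random trees: pruned distances equal the original submatrix exactly
  set.seed(42)
  for (i in 1:5) {
    tr10 <- simulate_tree(10, seed = NULL, height = NULL)
    keep <- sample(tr10$tip.label, 5)
    d_full <- ape::cophenetic.phylo(tr10)[keep, keep]
    d_sub <- ape::cophenetic.phylo(prune_to(tr10, keep))[keep, keep]
    expect_equal(d_sub, d_full)
  }

  expect_error(prune_to(tr, c("A", "Z")),
               class = "glandcov_missing_taxon_error")
})

test_that("Brownian covariance matches its definition and an edge-enumeration oracle", {
  tr <- read_newick_text("((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr, order = c("A", "B", "C"))
  expect_equal(unname(C), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3))

  st <- star_tree(5, len = 3)
  expect_equal(unname(bm_covariance(st)), 3 * diag(5))

  set.seed(7)
  for (i in 1:5) {
    tr8 <- simulate_tree(8, seed = NULL, height = NULL)
    expect_equal(bm_covariance(tr8), oracle_bm_covariance(tr8))
  }

  expect_error(bm_covariance(tr, order = c("A", "B")),
               class = "glandcov_alignment_error")
})

test_that("Brownian covariance is symmetric PSD; ultrametric trees have constant diagonal", {
  set.seed(11)
  for (i in 1:100) {
    tr <- simulate_tree(sample(4:12, 1), seed = NULL)
    C <- bm_covariance(tr)
    expect_equal(C, t(C))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(ev))
  }
  tr <- simulate_tree(10, seed = 5, height = 2.5)   # rphylo trees are ultrametric
  expect_equal(unname(diag(bm_covariance(tr))), rep(2.5, 10))
})

test_that("whitener is the symmetric inverse square root", {
  expect_equal(whitener(diag(4)), diag(4))
  expect_equal(whitener(4 * diag(3)), 0.5 * diag(3))

  set.seed(3)
  for (i in 1:5) {
    C <- random_spd(6)
    E <- whitener(C)
    expect_lt(max(abs(E %*% C %*% E - diag(6))), 1e-10)
    expect_lt(max(abs(E - t(E))), 1e-10)
  }

  Csing <- diag(c(1, 1, 1e-15))
  expect_error(whitener(Csing), class = "glandcov_conditioning_error")
  expect_error(whitener(matrix(1:9, 3)), class = "glandcov_conditioning_error")
})

test_that("GLS mean matches the explicit formula and reduces to arithmetic mean", {
  set.seed(9)
  Y <- matrix(rnorm(15), 5)
  expect_equal(gls_mean(diag(5), Y), colMeans(Y))
  expect_equal(gls_mean(3 * diag(5), Y), colMeans(Y))

  # constant column is returned unchanged regardless of C
  C <- random_spd(5)
  expect_equal(unname(gls_mean(C, matrix(7, 5, 1))), 7)

  # direct formula oracle
  one <- rep(1, 5)
  a_direct <- drop(solve(t(one) %*% solve(C) %*% one) %*% t(one) %*% solve(C) %*% Y)
  expect_equal(gls_mean(C, Y), a_direct)
})
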