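test_that("tree simulation is deterministic and respects the tip count", {
  t1 <- simulate_tree(12, seed = 3)
  t2 <- simulate_tree(12, seed = 3)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_length(t1$tip.label, 12)
  expect_true(all(t1$edge.length > 0))
  expect_equal(t1$tip.label, sprintf("sp%03d", 1:12))

  cherry <- simulate_tree(2, seed = 1)
  expect_length(cherry$tip.label, 2)

  # default rescaling to unit height
  expect_equal(max(ape::node.depth.edgelength(t1)[1:12]), 1)
})

test_that("Brownian simulation has the matrix-normal structure", {
  tr <- simulate_tree(6, seed = 1)
  expect_equal(unname(simulate_bm(tr, matrix(0), seed = 2)),
               matrix(0, 6, 1))

  # star tree, Sigma = I: entries are iid standard normal
  st <- star_tree(10)
  set.seed(5)
  draws <- replicate(1000, drop(simulate_bm(st, diag(1))))
  ks <- suppressWarnings(ks.test(as.vector(draws), "pnorm"))
  expect_gt(ks$p.value, 0.01)

  expect_error(simulate_bm(tr, matrix(c(1, 2, 0, 1), 2)),
               class = "glandcov_sim_error")
  expect_error(simulate_bm(tr, diag(c(1, -1))),
               class = "glandcov_sim_error")
})

test_that("Monte-Carlo covariance of BM draws converges to the tree covariance", {
  tr <- simulate_tree(5, seed = 7, height = NULL)
  C <- bm_covariance(tr)
  set.seed(99)
  draws <- t(replicate(2000, drop(simulate_bm(tr, matrix(1)))))
  Chat <- crossprod(draws) / 2000          # mean is 0 at the root
  expect_lt(max(abs(Chat - C)) / max(C), 0.10)
})

test_that("BM marginal variances scale linearly with tree height", {
  set.seed(13)
  tr1 <- simulate_tree(8, seed = 21, height = 1)
  tr4 <- tr1
  tr4$edge.length <- tr1$edge.length * 4
  v1 <- var(as.vector(replicate(800, drop(simulate_bm(tr1, matrix(1)))[1])))
  v4 <- var(as.vector(replicate(800, drop(simulate_bm(tr4, matrix(1)))[1])))
  expect_equal(v4 / v1, 4, tolerance = 0.4)
})

test_that("coupled blocks interpolate between independence and rank-one identity", {
  tr <- simulate_tree(16, seed = 31)
  b1 <- simulate_coupled_blocks(tr, 4, 3, rho = 1, seed = 5)
  r <- phylo_pls(b1$X1, b1$X2, tr, n_perm = 9, seed = 1)$r_pls
  expect_equal(r, 1, tolerance = 1e-8)

  # coupling strength along the true loading directions grows with rho
  # (the expected projected correlation is ~rho^2); raw mean r_PLS is not
  # monotone at weak coupling because of its small-sample null bias
  set.seed(41)
  w1 <- rep(1, 4) / 2; w2 <- rep(1, 3) / sqrt(3)
  mean_proj <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    mean(replicate(100, {
      b <- simulate_coupled_blocks(tr, 4, 3, rho = rho)
      cor(b$X1 %*% w1, b$X2 %*% w2)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_proj) > 0))
  expect_lt(abs(mean_proj[1]), 0.15)
  expect_gt(mean_proj[4], 0.6)

  # rho = 0 blocks are independent: the permutation test stays at level
  set.seed(43)
  rej0 <- mean(replicate(60, {
    b <- simulate_coupled_blocks(tr, 4, 3, rho = 0)
    phylo_pls(b$X1, b$X2, tr, n_perm = 99,
              seed = sample.int(1e6, 1))$p_value <= 0.05
  }))
  expect_lt(rej0, 0.15)
})

test_that("synthetic datasets satisfy the data-model invariants deterministically", {
  cfg <- sim_config(n_taxa = 10, n_bins = 40, effect_bins = 10:14,
                    seed = 8)
  d1 <- simulate_epg_dataset(cfg)
  d2 <- simulate_epg_dataset(cfg)
  expect_identical(d1$epg, d2$epg)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))

  expect_equal(unname(rowSums(d1$epg)), rep(1, 10))
  expect_true(all(d1$epg >= 0))
  expect_true(all(d1$compounds > 0))
  expect_equal(unname(rowSums(d1$classes)), rep(1, 10))
  expect_equal(ncol(d1$classes), 11)
  expect_setequal(rownames(d1$epg), d1$tree$tip.label)
  expect_equal(d1$complexity$species, rownames(d1$epg))
  expect_equal(d1$truth$effect_bins, 10:14)
})

test_that("null generator gives uniform regression p for the focal compound", {
  set.seed(55)
  pvals <- replicate(60, {
    cfg <- sim_config(n_taxa = 16, n_bins = 30, beta = 0, rho = 0,
                      effect_bins = 5:8, seed = sample.int(1e6, 1))
    ds <- simulate_epg_dataset(cfg)
    fit <- pgls_fit(clr(replace_zeros(ds$epg, "auto")), ds$compounds, ds$tree)
    anova_type3(fit, n_perm = 99,
                seed = sample.int(1e6, 1))$table$p_perm[1]
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
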