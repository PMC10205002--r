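test_that("with C = I coefficients equal textbook OLS", {
  set.seed(1)
  tr <- star_tree(14)
  X <- matrix(rnorm(14 * 2), 14, dimnames = list(tr$tip.label, c("a", "b")))
  y <- matrix(1 + 2 * X[, 1] - X[, 2] + rnorm(14),
              dimnames = list(tr$tip.label, "y"))
  fit <- pgls_fit(y, X, tr)
  ols <- lm(y ~ a + b, data = data.frame(y = y[, 1], X))
  expect_equal(unname(fit$coefficients[, 1]), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(fit$rss_full, sum(resid(ols)^2), tolerance = 1e-10)
})

test_that("noise-free linear responses are fitted exactly", {
  set.seed(2)
  tr <- simulate_tree(12, seed = 2)
  X <- simulate_bm(tr, diag(3))
  Y <- cbind(2 + X %*% c(1, -2, 0.5), -1 + X %*% c(0, 1, 1))
  fit <- pgls_fit(Y, X, tr)
  expect_lt(fit$rss_full, 1e-16)
  expect_equal(fit$fitted + fit$residuals, fit$response_t)
})

test_that("intercept-only fits return the phylogenetic mean", {
  set.seed(3)
  tr <- simulate_tree(9, seed = 3)
  Y <- simulate_bm(tr, diag(2))
  X0 <- matrix(numeric(0), nrow = 9, ncol = 0,
               dimnames = list(rownames(Y), NULL))
  fit <- pgls_fit(Y, X0, tr)
  C <- bm_covariance(tr, order = rownames(Y))
  expect_equal(unname(fit$coefficients[1, ]), unname(gls_mean(C, Y)))
})

test_that("pseudo-F with C = I univariate equals the classical partial F", {
  set.seed(4)
  tr <- star_tree(16)
  X <- matrix(rnorm(16 * 3), 16,
              dimnames = list(tr$tip.label, c("a", "b", "c")))
  y <- matrix(0.5 + X %*% c(1, 0, -0.5) + rnorm(16),
              dimnames = list(tr$tip.label, "y"))
  fit <- pgls_fit(y, X, tr)
  an <- anova_type3(fit, n_perm = 1, seed = 1)
  ols <- lm(y ~ a + b + c, data = data.frame(y = y[, 1], X))
  dr <- drop1(ols, test = "F")
  expect_equal(an$table$pseudo_F, dr[c("a", "b", "c"), "F value"],
               tolerance = 1e-8)
})

test_that("single-predictor type III SS equals sequential SS", {
  set.seed(5)
  tr <- simulate_tree(10, seed = 5)
  x <- simulate_bm(tr, matrix(1))
  y <- 2 * x + simulate_bm(tr, matrix(0.5))
  colnames(x) <- "x"; colnames(y) <- "y"
  fit <- pgls_fit(y, x, tr)
  an <- anova_type3(fit, n_perm = 9, seed = 1)
  # sequential SS for one term: RSS(intercept-only) - RSS(full)
  fit0 <- pgls_fit(y, matrix(numeric(0), 10, 0,
                             dimnames = list(rownames(y), NULL)), tr)
  expect_equal(an$table$SS, fit0$rss_full - fit$rss_full)
})

test_that("type III SS are invariant to predictor column order", {
  set.seed(6)
  tr <- simulate_tree(15, seed = 6)
  X <- simulate_bm(tr, diag(4))
  colnames(X) <- letters[1:4]
  Y <- simulate_bm(tr, diag(6))
  an1 <- anova_type3(pgls_fit(Y, X, tr), n_perm = 1, seed = 1)$table
  an2 <- anova_type3(pgls_fit(Y, X[, c(3, 1, 4, 2)], tr),
                     n_perm = 1, seed = 1)$table
  expect_equal(an1$SS, an2$SS[match(an1$term, an2$term)])
  expect_equal(an1$pseudo_F, an2$pseudo_F[match(an1$term, an2$term)])
})

test_that("predictions are affine in the focal value and hit the centroid", {
  set.seed(7)
  tr <- simulate_tree(12, seed = 7)
  X <- simulate_bm(tr, diag(3))
  colnames(X) <- c("a", "b", "c")
  Y <- simulate_bm(tr, diag(5)) + X[, "a"] %o% rep(1, 5)
  fit <- pgls_fit(Y, X, tr)
  at <- c(-1, 0, 1, 3)
  pr <- predict_response(fit, "a", at)
  # collinearity: prediction at 1 lies on the segment from -1 to 3
  lam <- (1 - (-1)) / (3 - (-1))
  expect_equal(pr[3, ], (1 - lam) * pr[1, ] + lam * pr[4, ])
  # focal at its GLS mean reproduces the all-means prediction
  C <- bm_covariance(tr, order = rownames(Y))
  xbar <- gls_mean(C, X)
  pr_bar <- predict_response(fit, "a", xbar["a"])
  expect_equal(drop(pr_bar), drop(c(1, xbar) %*% fit$coefficients))
  expect_error(predict_response(fit, "zzz", 1), class = "glandcov_pgls_error")
})

test_that("responsive regions are thresholded runs of the difference profile", {
  lo <- rep(0, 50)
  hi <- rep(0, 50); hi[10:14] <- 1
  rg <- responsive_regions(lo, hi, min_run = 2, frac_of_max = 0.5)
  expect_equal(nrow(rg), 1)
  expect_equal(c(rg$start_bin, rg$end_bin), c(10, 14))
  expect_equal(rg$delta, 1)

  # flat positive difference: one degenerate region spanning everything
  expect_warning(rg2 <- responsive_regions(rep(0, 20), rep(0.3, 20)),
                 "flat")
  expect_equal(c(rg2$start_bin, rg2$end_bin), c(1, 20))

  # three bumps, heights 1.0 / 0.8 / 0.1 at frac 0.5: exactly two survive
  hi3 <- rep(0, 60)
  hi3[5:8] <- 1; hi3[20:23] <- 0.8; hi3[40:43] <- 0.1
  rg3 <- responsive_regions(rep(0, 60), hi3, min_run = 2, frac_of_max = 0.5)
  expect_equal(nrow(rg3), 2)
  expect_equal(sort(rg3$start_bin), c(5, 20))
  expect_equal(rg3$delta[1], 1)   # sorted by decreasing magnitude

  # nothing responds positively: empty report, not an error
  expect_equal(nrow(responsive_regions(rep(1, 10), rep(0, 10))), 0)

  # kDa calibration is carried through
  kda <- seq(250, 10, length.out = 50)
  rgk <- responsive_regions(lo, hi, kda = kda)
  expect_equal(rgk$start_kda, kda[10])
  expect_equal(rgk$end_kda, kda[14])
})

test_that("complexity regression recovers a known slope on a star tree", {
  set.seed(8)
  tr <- star_tree(30)
  slopes <- replicate(50, {
    x <- rnorm(30)
    y <- 2 * x + rnorm(30, sd = 0.5)
    names(x) <- names(y) <- tr$tip.label
    complexity_regression(y, x, tr, n_perm = 1, seed = 1)$slope
  })
  expect_equal(mean(slopes), 2, tolerance = 0.05)
  expect_gt(min(slopes), 1.5)
  expect_lt(max(slopes), 2.5)
})

test_that("complexity regression p-values are uniform under the null", {
  set.seed(9)
  tr <- simulate_tree(20, seed = 9)
  pvals <- replicate(100, {
    x <- drop(simulate_bm(tr, matrix(1)))
    y <- drop(simulate_bm(tr, matrix(1)))
    complexity_regression(y, x, tr, n_perm = 99,
                          seed = sample.int(1e6, 1))$anova$table$p_perm
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("perfect fits report capped statistics instead of failing", {
  tr <- simulate_tree(10, seed = 10)
  x <- drop(simulate_bm(tr, matrix(1), seed = 11))
  names(x) <- tr$tip.label
  res <- complexity_regression(x, x, tr, n_perm = 99, seed = 1)
  expect_equal(res$anova$rss_full, 0)
  expect_equal(res$anova$table$pseudo_F, 1e15)
  expect_equal(res$anova$table$p_perm, 1 / 100)
})

test_that("confidence band widens away from the data centroid", {
  set.seed(12)
  tr <- star_tree(25)
  x <- rnorm(25); y <- 1 + 0.5 * x + rnorm(25)
  names(x) <- names(y) <- tr$tip.label
  res <- complexity_regression(y, x, tr, n_perm = 1, seed = 1)
  w <- res$line$upr - res$line$lwr
  expect_true(all(w > 0))
  expect_gt(w[1], min(w))      # edges wider than the narrowest point
  expect_gt(w[100], min(w))
})
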