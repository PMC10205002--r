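#' Phylogenetic regression via generalized least squares
#'
#' Fits a (possibly multivariate) linear model of `Y` on `X` after the
#' Brownian-motion transform: both the response and the design (intercept
#' plus predictors) are premultiplied by the inverse principal square root
#' of the tree covariance, and ordinary least squares is applied in the
#' transformed space. Each response column shares the same design, so the
#' fit scales to responses with many more variables than species.
#'
#' @param Y Species x q response matrix (row names = species).
#' @param X Species x k predictor matrix (row names = species).
#' @param tree `phylo` tree over the same species.
#' @return Object of class `pgls_fit`: coefficients ((k+1) x q), fitted
#'   values and residuals in transformed space, `rss_full`, the tree
#'   covariance `C`, whitener `E`, and the original blocks.
#' @export
pgls_fit <- function(Y, X, tree) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  al <- align_blocks(list(Y, X), tree)
  Y <- al$mats[[1]]; X <- al$mats[[2]]; tree <- al$tree
  n <- nrow(Y)
  k <- ncol(X)
  if (n <= k + 1L) {
    stop_glandcov("pgls", "need n > number of predictors + 1 (n = ", n,
                  ", k = ", k, ")")
  }
  C <- bm_covariance(tree, order = rownames(Y))
  E <- whitener(C)
  D <- cbind(`(Intercept)` = 1, X)
  Dt <- E %*% D
  Yt <- E %*% Y
  qrD <- qr(Dt)
  if (qrD$rank < ncol(Dt)) {
    stop_glandcov("pgls", "design is rank-deficient (collinear predictors)")
  }
  coefs <- qr.coef(qrD, Yt)
  fitted <- qr.fitted(qrD, Yt)
  resid <- Yt - fitted
  structure(list(
    coefficients = coefs,
    fitted = fitted,
    residuals = resid,
    rss_full = sum(resid^2),
    design_labels = colnames(X),
    Y = Y, X = X, tree = tree, C = C, E = E,
    design = D, design_t = Dt, response_t = Yt, qr = qrD
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS fit: %d species, %d predictor(s), %d response column(s)\n",
              nrow(x$Y), length(x$design_labels), ncol(x$Y)))
  cat(sprintf("  residual SS (transformed space): %.6g\n", x$rss_full))
  invisible(x)
}

# residual-maker matrix I - H for a design in transformed space
resid_maker <- function(Dt) {
  qd <- qr(Dt)
  Q <- qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]
  diag(nrow(Dt)) - tcrossprod(Q)
}

#' Marginal (type III) ANOVA with residual-randomization significance
#'
#' For each predictor, the marginal sum of squares is the increase in
#' residual sum of squares when that predictor alone is dropped from the
#' full model; pseudo-F is the marginal SS over the full-model residual
#' mean square. Significance uses RRPP: residuals of the reduced
#' (term-dropped) model are row-permuted, added back to the reduced fitted
#' values, and the pseudo-F recomputed, with one shared permutation-index
#' stream across terms so p-values are comparable within a run. The
#' p-value convention is (b + 1)/(m + 1), counting the observed statistic
#' and ties as exceedances.
#'
#' Degenerate perfect fits (residual SS of the full model numerically
#' zero) report a capped pseudo-F and the minimal attainable p-value
#' rather than failing.
#'
#' @param fit A [pgls_fit()] object.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `anova_rrpp`: data.frame `table` with columns
#'   term, df, SS, pseudo_F, p_perm, plus `df_res`, `rss_full`, `n_perm`,
#'   `seed`.
#' @export
anova_type3 <- function(fit, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(fit, "pgls_fit"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop_glandcov("pgls", "n_perm must be >= 1")
  terms <- fit$design_labels
  n <- nrow(fit$response_t)
  p_full <- ncol(fit$design_t)
  df_res <- n - p_full
  if (df_res <= 0L) stop_glandcov("pgls", "no residual degrees of freedom")

  Yt <- fit$response_t
  M_full <- resid_maker(fit$design_t)
  rss_full <- sum((M_full %*% Yt)^2)

  red <- lapply(terms, function(tm) {
    Dr <- fit$design_t[, setdiff(colnames(fit$design_t), tm), drop = FALSE]
    Mr <- resid_maker(Dr)
    res_r <- Mr %*% Yt
    list(M = Mr, fitted = Yt - res_r, resid = res_r, rss = sum(res_r^2))
  })
  names(red) <- terms

  ss <- vapply(red, function(r) r$rss - rss_full, numeric(1))
  ss <- pmax(ss, 0)
  df_term <- rep(1L, length(terms))
  tiny <- 1e-12 * max(sum(Yt^2), 1)

  if (rss_full <= tiny) {
    tab <- data.frame(term = terms, df = df_term, SS = ss,
                      pseudo_F = rep(1e15, length(terms)),
                      p_perm = rep(1 / (n_perm + 1), length(terms)))
    return(structure(list(table = tab, df_res = df_res, rss_full = 0,
                          n_perm = n_perm, seed = as.integer(seed)),
                     class = "anova_rrpp"))
  }

  F_obs <- (ss / df_term) / (rss_full / df_res)

  set.seed(as.integer(seed))
  perms <- lapply(seq_len(n_perm), function(i) sample.int(n))
  exceed <- numeric(length(terms))
  for (pm in perms) {
    for (j in seq_along(terms)) {
      Yp <- red[[j]]$fitted + red[[j]]$resid[pm, , drop = FALSE]
      rss_f <- sum((M_full %*% Yp)^2)
      rss_r <- sum((red[[j]]$M %*% Yp)^2)
      Fp <- if (rss_f <= tiny) 1e15 else
        ((rss_r - rss_f) / df_term[j]) / (rss_f / df_res)
      if (Fp >= F_obs[j] - 1e-12) exceed[j] <- exceed[j] + 1
    }
  }
  p <- (1 + exceed) / (n_perm + 1)

  tab <- data.frame(term = terms, df = df_term, SS = ss,
                    pseudo_F = F_obs, p_perm = p)
  structure(list(table = tab, df_res = df_res, rss_full = rss_full,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "anova_rrpp")
}

#' @export
print.anova_rrpp <- function(x, ...) {
  cat(sprintf("Marginal (type III) ANOVA, RRPP with %d permutations\n", x$n_perm))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Residuals: df = %d, SS = %.6g\n", x$df_res, x$rss_full))
  invisible(x)
}

#' Predicted responses along one predictor
#'
#' Evaluates the fitted model at chosen values of a focal predictor while
#' holding every other predictor at its phylogenetic (GLS) mean, on the
#' original (untransformed) design scale. Predictions are on the
#' response's analysis scale (CLR, for compositional responses); set
#' `backtransform = TRUE` for the compositional view.
#'
#' @param fit A [pgls_fit()] object.
#' @param term Name of the focal predictor.
#' @param at_values Numeric values for the focal predictor.
#' @param backtransform Apply [clr_inverse()] to each predicted row.
#' @return length(at_values) x q matrix of predictions.
#' @export
predict_response <- function(fit, term, at_values, backtransform = FALSE) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (!term %in% fit$design_labels) {
    stop_glandcov("pgls", "unknown term '", term, "'; design has: ",
                  paste(fit$design_labels, collapse = ", "))
  }
  at_values <- as.numeric(at_values)
  if (any(!is.finite(at_values))) stop_glandcov("pgls", "non-finite at_values")
  xbar <- gls_mean(fit$C, fit$X)
  newD <- t(vapply(at_values, function(a) {
    x <- xbar
    x[term] <- a
    c(1, x)
  }, numeric(ncol(fit$design))))
  pred <- newD %*% fit$coefficients
  rownames(pred) <- format(at_values, trim = TRUE)
  if (backtransform) pred <- clr_inverse(pred)
  pred
}

#' Localize responsive profile regions
#'
#' Given predicted profiles at a low and a high value of a focal
#' predictor, the difference profile is thresholded at a fraction of its
#' maximum and maximal runs of at least `min_run` consecutive
#' above-threshold bins are reported as responsive regions, ordered by
#' decreasing effect magnitude. When a bin-to-kDa calibration is supplied
#' the bounds are also reported in kDa.
#'
#' @param pred_lo,pred_hi Equal-length predicted profiles (CLR scale).
#' @param min_run Minimum number of consecutive bins in a region.
#' @param frac_of_max Threshold as a fraction of the maximum difference.
#' @param kda Optional numeric vector of per-bin kDa values.
#' @return data.frame (start_bin, end_bin, start_kda, end_kda, delta),
#'   sorted by decreasing `abs(delta)`; zero rows when no bin responds
#'   positively.
#' @export
responsive_regions <- function(pred_lo, pred_hi, min_run = 2L,
                               frac_of_max = 0.5, kda = NULL) {
  pred_lo <- as.numeric(pred_lo)
  pred_hi <- as.numeric(pred_hi)
  if (length(pred_lo) != length(pred_hi)) {
    stop_glandcov("region", "profiles must have equal length")
  }
  if (frac_of_max <= 0 || frac_of_max >= 1) {
    stop_glandcov("region", "frac_of_max must be in (0, 1)")
  }
  delta <- pred_hi - pred_lo
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      start_kda = numeric(0), end_kda = numeric(0),
                      delta = numeric(0))
  if (max(delta) <= 0) return(empty)
  if (diff(range(delta)) < 1e-12) {
    warning("difference profile is flat; one region spans all bins")
  }
  above <- delta >= frac_of_max * max(delta)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (!length(keep)) return(empty)
  out <- data.frame(
    start_bin = starts[keep], end_bin = ends[keep],
    start_kda = if (is.null(kda)) NA_real_ else kda[starts[keep]],
    end_kda = if (is.null(kda)) NA_real_ else kda[ends[keep]],
    delta = vapply(keep, function(j)
      max(delta[starts[j]:ends[j]]), numeric(1))
  )
  out[order(-abs(out$delta)), , drop = FALSE]
}

#' Univariate complexity regression on the tree
#'
#' Relates a protein-complexity scalar (peak richness R_P or entropy H_P)
#' to its lipid counterpart (R_L or H_L) with the same distance-based
#' machinery as the multivariate model: a single-predictor phylogenetic
#' GLS fit tested by RRPP. Also returns the fitted line with a 95%
#' confidence band computed from transformed-space standard errors
#' (t-quantile, residual degrees of freedom).
#'
#' @param y,x Named numeric vectors (names = species) or unnamed vectors
#'   ordered as the tree tips.
#' @param tree `phylo` tree.
#' @param n_perm,seed Passed to [anova_type3()].
#' @param xname,yname Labels used in the output.
#' @return List: `fit` (pgls_fit), `anova` (anova_rrpp), `slope`,
#'   `intercept`, `line` (data.frame x, fit, lwr, upr).
#' @export
complexity_regression <- function(y, x, tree, n_perm = 999L, seed = 1L,
                                  xname = "x", yname = "y") {
  y <- as_species_matrix(y, tree, yname)
  x <- as_species_matrix(x, tree, xname)
  fit <- pgls_fit(y, x, tree)
  an <- anova_type3(fit, n_perm = n_perm, seed = seed)

  b <- fit$coefficients[, 1L]
  df_res <- nrow(y) - 2L
  sigma2 <- fit$rss_full / df_res
  XtXi <- chol2inv(chol(crossprod(fit$design_t)))
  xg <- seq(min(x), max(x), length.out = 100L)
  se <- vapply(xg, function(x0) {
    v <- c(1, x0)
    sqrt(sigma2 * drop(t(v) %*% XtXi %*% v))
  }, numeric(1))
  pred <- b[1L] + b[2L] * xg
  tq <- stats::qt(0.975, df_res)
  list(fit = fit, anova = an,
       slope = unname(b[2L]), intercept = unname(b[1L]),
       line = data.frame(x = xg, fit = pred,
                         lwr = pred - tq * se, upr = pred + tq * se))
}

as_species_matrix <- function(v, tree, name) {
  if (is.matrix(v)) {
    colnames(v) <- name
    return(v)
  }
  m <- matrix(as.numeric(v), ncol = 1L, dimnames = list(names(v), name))
  if (is.null(rownames(m))) rownames(m) <- tree$tip.label
  m
}
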