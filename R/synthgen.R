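#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. Defaults mirror the
#' shape of the study data: 36 species, 300-bin electrophoretic profiles,
#' 8 target compounds. `rho` couples a latent Brownian factor across the
#' profile and compound blocks; `beta` injects a linear effect of the
#' first compound onto `effect_bins` of the latent (CLR-scale) profile;
#' `noise_sd` is iid within-bin noise on that scale.
#'
#' @param n_taxa Number of species (>= 4).
#' @param n_bins Profile bins.
#' @param n_compounds Number of target compounds.
#' @param rho Cross-block latent correlation in \[0, 1\].
#' @param effect_bins Bin indices (1-based) receiving the injected effect.
#' @param beta Effect size, CLR units per unit compound abundance.
#' @param noise_sd Within-species iid noise SD on the latent profile.
#' @param birth_rate Speciation rate of the pure-birth tree.
#' @param n_pool Size of the full GC-MS compound pool from which lipid
#'   richness and entropy are computed (the 8 target compounds are a
#'   subset of interest, but richness counts every detected compound).
#' @param detect_quantile Fraction of pool abundances falling below the
#'   detection limit (species-level zeros), so richness varies.
#' @param seed Integer seed; every draw is a pure function of (config, seed).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 36L, n_bins = 300L, n_compounds = 8L,
                       rho = 0.5, effect_bins = 40:45, beta = 1,
                       noise_sd = 0.25, birth_rate = 1,
                       n_pool = 60L, detect_quantile = 0.25, seed = 1L) {
  stopifnot(n_taxa >= 4L, n_bins >= 10L, n_compounds >= 2L,
            rho >= 0, rho <= 1,
            all(effect_bins >= 1L), all(effect_bins <= n_bins),
            noise_sd >= 0, birth_rate > 0, n_pool >= 4L,
            detect_quantile >= 0, detect_quantile < 1)
  structure(list(n_taxa = as.integer(n_taxa), n_bins = as.integer(n_bins),
                 n_compounds = as.integer(n_compounds), rho = rho,
                 effect_bins = as.integer(effect_bins), beta = beta,
                 noise_sd = noise_sd, birth_rate = birth_rate,
                 n_pool = as.integer(n_pool),
                 detect_quantile = detect_quantile,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Constant-rate pure-birth tree conditioned on the number of tips, via
#' [ape::rphylo()] with zero extinction. Tips are labeled `sp001`,
#' `sp002`, ... in tip order. By default the tree is rescaled to unit
#' height so downstream Brownian variances are on a predictable scale
#' (branch-length units are arbitrary for a simulated clade).
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional integer seed (`NULL` continues the current RNG
#'   stream).
#' @param height Rescale tree height to this value; `NULL` keeps the raw
#'   simulated depth.
#' @return A `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL, height = 1) {
  stopifnot(n_taxa >= 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- ape::rphylo(as.integer(n_taxa), birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(n_taxa))
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(tr)[seq_len(n_taxa)])
    tr$edge.length <- tr$edge.length * (height / h)
  }
  tr
}

# symmetric principal square root with eigenvalue clipping at zero,
# so degenerate PSD matrices are handled
sym_sqrt <- function(S) {
  S <- as.matrix(S)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  eg$vectors %*% (t(eg$vectors) * sqrt(lam))
}

#' Simulate correlated traits under Brownian motion on a tree
#'
#' Draws one matrix-normal sample with row covariance `C` (the tree's
#' Brownian covariance) and column covariance `Sigma`:
#' `X = sqrtm(C) %*% Z %*% sqrtm(Sigma)` with `Z` iid standard normal.
#'
#' @param tree `phylo` tree.
#' @param Sigma q x q symmetric PSD trait covariance (scalar allowed for
#'   q = 1).
#' @param seed Optional integer seed (`NULL` continues the current RNG
#'   stream).
#' @return n_tips x q matrix with tip labels as row names.
#' @export
simulate_bm <- function(tree, Sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(Sigma, tol = 1e-8)) {
    stop_glandcov("sim", "Sigma must be symmetric")
  }
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop_glandcov("sim", "Sigma must be positive semidefinite")
  }
  C <- bm_covariance(tree)
  n <- nrow(C)
  q <- ncol(Sigma)
  Z <- matrix(stats::rnorm(n * q), n, q)
  X <- sym_sqrt(C) %*% Z %*% t(sym_sqrt(Sigma))
  rownames(X) <- rownames(C)
  X
}

#' Simulate two trait blocks with a shared latent Brownian factor
#'
#' One latent Brownian factor `f` evolves on the tree; block j is
#' `rho * f w_j' + sqrt(1 - rho^2) * N_j` with fixed unit loading vectors
#' `w_j` and independent Brownian noise `N_j`. `rho = 0` gives exactly
#' independent blocks; `rho = 1` makes both blocks rank-one functions of
#' the same factor.
#'
#' @param tree `phylo` tree.
#' @param p1,p2 Number of variables in each block.
#' @param rho Latent cross-block correlation in \[0, 1\].
#' @param seed Optional integer seed.
#' @return List with matrices `X1`, `X2` and the latent `f`.
#' @export
simulate_coupled_blocks <- function(tree, p1, p2, rho, seed = NULL) {
  stopifnot(rho >= 0, rho <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- simulate_bm(tree, matrix(1))
  w1 <- rep(1, p1) / sqrt(p1)
  w2 <- rep(1, p2) / sqrt(p2)
  N1 <- simulate_bm(tree, diag(p1))
  N2 <- simulate_bm(tree, diag(p2))
  X1 <- rho * f %*% t(w1) + sqrt(1 - rho^2) * N1
  X2 <- rho * f %*% t(w2) + sqrt(1 - rho^2) * N2
  rownames(X1) <- rownames(X2) <- rownames(f)
  list(X1 = X1, X2 = X2, f = drop(f))
}

#' Simulate a full synthetic secretion dataset with known ground truth
#'
#' Generates, from a single seed: a pure-birth tree; eight positive
#' compound abundances as exponentiated Brownian latents sharing a latent
#' factor with the profile block (coupling `rho`); a 300-bin
#' compositional profile obtained by inverse-CLR of a latent Brownian
#' baseline plus an injected linear effect of compound 1 on
#' `effect_bins`; an 11-class logistic-normal composition table (closure
#' of exponentiated Brownian latents); and the four complexity scalars computed by the
#' profile module on the generated data. The injected truth (`rho`,
#' `effect_bins`, `beta`) is recorded for recovery tests.
#'
#' The profile coupling uses a fixed smooth (Gaussian-bump) loading
#' across bins: a constant loading would shift every bin equally and be
#' annihilated by the CLR, making `rho` invisible to the analysis.
#'
#' @param cfg A [sim_config()].
#' @return List of class `synthetic_dataset`: `tree`, `epg`, `compounds`,
#'   `classes`, `complexity`, `truth`, `config`.
#' @export
simulate_epg_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_taxa, cfg$birth_rate, seed = NULL)
  n <- cfg$n_taxa
  nb <- cfg$n_bins
  nc <- cfg$n_compounds

  # loadings are normalized to unit maximum so rho is the latent
  # correlation between the factor and each fully-loaded variable;
  # unit-norm loadings would dilute the factor to nothing in wide blocks
  f <- simulate_bm(tree, matrix(1))
  mix <- function(W, w) cfg$rho * f %*% t(w) + sqrt(1 - cfg$rho^2) * W

  # compounds: exponentiated BM latents sharing the factor; loadings form
  # a signed gradient across compounds (a constant loading would shift
  # all compounds together and vanish from the closed composition)
  lat_comp <- mix(simulate_bm(tree, diag(nc)), seq(1, -1, length.out = nc))
  compounds <- exp(lat_comp)
  colnames(compounds) <- sprintf("compound_%d", seq_len(nc))

  # latent CLR-scale profile: the factor loads on a smooth Gaussian bump
  # of bins (a constant loading would be annihilated by the CLR)
  ctr <- nb / 3
  wb <- exp(-((seq_len(nb) - ctr)^2) / (2 * (nb / 10)^2))
  base <- mix(simulate_bm(tree, diag(nb)), wb)
  eff <- matrix(0, n, nb)
  eff[, cfg$effect_bins] <- cfg$beta * compounds[, 1L]
  latent <- base + eff + matrix(stats::rnorm(n * nb, sd = cfg$noise_sd), n, nb)
  epg <- clr_inverse(latent)
  colnames(epg) <- sprintf("bin%03d", seq_len(nb))

  # logistic-normal class composition: closure of exponentiated BM
  # latents, the standard compositional model; its CLR is exactly
  # matrix-normal on the tree, so permutation nulls stay calibrated
  classes <- closure_rows(exp(simulate_bm(tree, diag(11))))
  colnames(classes) <- sprintf("class_%02d", 1:11)

  # full GC-MS compound pool: lognormal abundances with a detection
  # limit, so lipid richness and entropy vary across species
  pool <- exp(mix(simulate_bm(tree, diag(cfg$n_pool)),
                  rep(1, cfg$n_pool) / sqrt(cfg$n_pool)))
  thr <- stats::quantile(pool, cfg$detect_quantile)
  pool[pool < thr] <- 0
  colnames(pool) <- sprintf("pool_%02d", seq_len(cfg$n_pool))

  complexity <- complexity_table(epg, pool)

  structure(list(
    tree = tree, epg = epg, compounds = compounds, classes = classes,
    pool = pool, complexity = complexity,
    truth = list(rho = cfg$rho, effect_bins = cfg$effect_bins,
                 beta = cfg$beta),
    config = cfg
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic secretion dataset: %d species, %d profile bins, %d compounds\n",
              nrow(x$epg), ncol(x$epg), ncol(x$compounds)))
  cat(sprintf("  truth: rho = %.2f, beta = %.2f on bins %d-%d\n",
              x$truth$rho, x$truth$beta,
              min(x$truth$effect_bins), max(x$truth$effect_bins)))
  invisible(x)
}
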