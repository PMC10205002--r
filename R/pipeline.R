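#' Write a dataset to a directory of plain-text files
#'
#' Writes `tree.nwk`, `epg.csv`, `compounds.csv`, `classes.csv`,
#' `complexity.csv` and (for synthetic data) `truth.json`. CSVs are
#' comma-separated UTF-8 with a mandatory `species` first column.
#'
#' @param ds A `synthetic_dataset` or `gland_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  wr <- function(M, name) {
    df <- data.frame(species = rownames(M), as.data.frame(M),
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(ds$epg, "epg.csv")
  wr(ds$compounds, "compounds.csv")
  wr(ds$classes, "classes.csv")
  utils::write.csv(ds$complexity, file.path(dir, "complexity.csv"),
                   row.names = FALSE)
  if (!is.null(ds$truth)) {
    jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a dataset from CSV files and a Newick tree
#'
#' Reads the species-by-variable tables, validates them (numeric cells,
#' no missing values, unique species, exact case-sensitive agreement with
#' the tree's tip set) and aligns every matrix to the tree's tip order,
#' which is the canonical row order for all downstream analysis.
#'
#' @param dir Directory containing `tree.nwk`, `epg.csv`,
#'   `compounds.csv`, `classes.csv`, `complexity.csv` (as written by
#'   [write_dataset()]); alternatively supply `paths`.
#' @param paths Optional named list overriding individual file paths
#'   (`tree`, `epg`, `compounds`, `classes`, `complexity`).
#' @return List of class `gland_dataset`.
#' @export
load_dataset <- function(dir = NULL, paths = list()) {
  defaults <- c(tree = "tree.nwk", epg = "epg.csv",
                compounds = "compounds.csv", classes = "classes.csv",
                complexity = "complexity.csv")
  p <- lapply(names(defaults), function(nm) {
    if (!is.null(paths[[nm]])) paths[[nm]] else file.path(dir, defaults[[nm]])
  })
  names(p) <- names(defaults)
  tree <- read_newick(p$tree)
  tips <- tree$tip.label

  read_mat <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1L] != "species") {
      stop_glandcov("io", basename(path), ": first column must be 'species'")
    }
    sp <- as.character(df$species)
    if (anyDuplicated(sp)) {
      stop_glandcov("io", basename(path), ": duplicate species rows: ",
                    paste(unique(sp[duplicated(sp)]), collapse = ", "))
    }
    M <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(M)) {
      stop_glandcov("io", basename(path), ": non-numeric cells")
    }
    if (anyNA(M)) stop_glandcov("io", basename(path), ": missing values")
    rownames(M) <- sp
    miss <- setdiff(tips, sp)
    extra <- setdiff(sp, tips)
    if (length(miss) || length(extra)) {
      stop_glandcov("alignment", basename(path), ": species mismatch",
                    if (length(miss)) paste0("; in tree but not table: ",
                                             paste(miss, collapse = ", ")),
                    if (length(extra)) paste0("; in table but not tree: ",
                                              paste(extra, collapse = ", ")))
    }
    M[tips, , drop = FALSE]
  }

  epg <- read_mat(p$epg)
  compounds <- read_mat(p$compounds)
  classes <- read_mat(p$classes)
  cx <- utils::read.csv(p$complexity)
  if (!all(c("species", "R_P", "H_P", "R_L", "H_L") %in% names(cx))) {
    stop_glandcov("io", "complexity table needs columns species, R_P, H_P, R_L, H_L")
  }
  cx <- cx[match(tips, cx$species), , drop = FALSE]
  if (anyNA(cx)) stop_glandcov("alignment", "complexity table species mismatch")

  structure(list(tree = tree, epg = epg, compounds = compounds,
                 classes = classes, complexity = cx, truth = NULL,
                 paths = p),
            class = "gland_dataset")
}

#' Run the full three-stage covariation analysis
#'
#' Reproduces the study design end to end on any dataset with the study's
#' shape: (1) phylogenetic two-block PLS of the CLR-transformed profile
#' matrix against the CLR class composition, and against the CLR of the
#' closed eight-compound relative abundances; (2) phylogenetic regression
#' of the profiles on the absolute compound abundances with marginal
#' (type III) RRPP tests, followed, for each flagged compound, by model
#' predictions at its observed minimum and maximum and localization of
#' responsive profile regions; (3) univariate complexity regressions
#' R_P ~ R_L and H_P ~ H_L.
#'
#' Compound flagging for the region follow-up uses Holm-adjusted
#' permutation p-values across the eight marginal tests by default
#' (`p_adjust = "none"` flags on raw p < 0.05). All stage-level seeds are
#' derived from `seed` as `seed + 1, seed + 2, ...` in stage order.
#'
#' @param ds A `gland_dataset` or `synthetic_dataset`.
#' @param n_perm Permutations for every test (study setting: 9999).
#' @param seed Integer master seed.
#' @param zero_delta Zero-replacement value or `"auto"` (half the smallest
#'   positive entry, per matrix).
#' @param response_transform `"clr"` (default) analyses the CLR of the
#'   row-normalized profiles; `"none"` uses the normalized profiles as-is.
#' @param p_adjust `"holm"` or `"none"`: multiplicity handling for
#'   flagging compounds in stage 2.
#' @param alpha Significance level for flagging (default 0.05).
#' @param min_run,frac_of_max Passed to [responsive_regions()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV plus a JSON run manifest.
#' @return List of class `gland_analysis` with elements `pls_classes`,
#'   `pls_compounds`, `pgls` (fit, anova, flagged, predictions, regions),
#'   `complexity` (richness, entropy), `config`.
#' @export
run_full_analysis <- function(ds, n_perm = 999L, seed = 1L,
                              zero_delta = "auto",
                              response_transform = c("clr", "none"),
                              p_adjust = c("holm", "none"),
                              alpha = 0.05,
                              min_run = 2L, frac_of_max = 0.5,
                              out_dir = NULL) {
  response_transform <- match.arg(response_transform)
  p_adjust <- match.arg(p_adjust)
  tree <- ds$tree
  tips <- tree$tip.label
  epg <- closure_rows(ds$epg[tips, , drop = FALSE])
  compounds <- ds$compounds[tips, , drop = FALSE]
  classes <- ds$classes[tips, , drop = FALSE]

  epg_clr <- clr(replace_zeros(epg, zero_delta))
  classes_clr <- clr(replace_zeros(closure_rows(classes), zero_delta))
  compounds_rel <- closure_rows(compounds)
  compounds_clr <- clr(replace_zeros(compounds_rel, zero_delta))
  response <- if (response_transform == "clr") epg_clr else epg

  # stage 1: covariation
  pls_classes <- phylo_pls(epg_clr, classes_clr, tree,
                           n_perm = n_perm, seed = seed + 1L)
  pls_compounds <- phylo_pls(epg_clr, compounds_clr, tree,
                             n_perm = n_perm, seed = seed + 2L)

  # stage 2: which compounds drive the profile, and where
  fit <- pgls_fit(response, compounds, tree)
  an <- anova_type3(fit, n_perm = n_perm, seed = seed + 3L)
  tab <- an$table
  tab$p_adj <- stats::p.adjust(tab$p_perm,
                               method = if (p_adjust == "none") "none" else "holm")
  flagged <- tab$term[tab$p_adj < alpha]
  predictions <- stats::setNames(list(), character(0))
  regions <- stats::setNames(list(), character(0))
  for (tm in flagged) {
    rng <- range(compounds[, tm])
    pr <- predict_response(fit, tm, rng)
    predictions[[tm]] <- pr
    regions[[tm]] <- responsive_regions(pr[1L, ], pr[2L, ],
                                        min_run = min_run,
                                        frac_of_max = frac_of_max)
  }

  # stage 3: complexity coupling
  cx <- ds$complexity
  rownames(cx) <- cx$species
  cx <- cx[tips, , drop = FALSE]
  reg_R <- complexity_regression(stats::setNames(cx$R_P, tips),
                                 stats::setNames(cx$R_L, tips), tree,
                                 n_perm = n_perm, seed = seed + 4L,
                                 xname = "R_L", yname = "R_P")
  reg_H <- complexity_regression(stats::setNames(cx$H_P, tips),
                                 stats::setNames(cx$H_L, tips), tree,
                                 n_perm = n_perm, seed = seed + 5L,
                                 xname = "H_L", yname = "H_P")

  res <- structure(list(
    pls_classes = pls_classes,
    pls_compounds = pls_compounds,
    pgls = list(fit = fit, anova = an, table = tab, flagged = flagged,
                predictions = predictions, regions = regions),
    complexity = list(richness = reg_R, entropy = reg_H),
    config = list(n_perm = n_perm, seed = seed, zero_delta = zero_delta,
                  response_transform = response_transform,
                  p_adjust = p_adjust, alpha = alpha,
                  min_run = min_run, frac_of_max = frac_of_max,
                  package_version = as.character(utils::packageVersion("glandcov")))
  ), class = "gland_analysis")

  if (!is.null(out_dir)) write_analysis(res, ds, out_dir)
  res
}

#' @export
print.gland_analysis <- function(x, ...) {
  cat("Protein-lipid covariation analysis\n")
  cat(sprintf("  [1] PLS profile~classes:   r_PLS = %.3f, P = %.4g\n",
              x$pls_classes$r_pls, x$pls_classes$p_value))
  cat(sprintf("      PLS profile~compounds: r_PLS = %.3f, P = %.4g\n",
              x$pls_compounds$r_pls, x$pls_compounds$p_value))
  cat("  [2] Marginal (type III) tests of compounds on the profile:\n")
  print(x$pgls$table, row.names = FALSE, digits = 4)
  cat(sprintf("      flagged: %s\n",
              if (length(x$pgls$flagged)) paste(x$pgls$flagged, collapse = ", ")
              else "(none)"))
  cat(sprintf("  [3] R_P~R_L: pseudo-F = %.3f, P = %.4g | H_P~H_L: pseudo-F = %.3f, P = %.4g\n",
              x$complexity$richness$anova$table$pseudo_F,
              x$complexity$richness$anova$table$p_perm,
              x$complexity$entropy$anova$table$pseudo_F,
              x$complexity$entropy$anova$table$p_perm))
  invisible(x)
}

write_analysis <- function(res, ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(data.frame(analysis = c("profile_vs_classes", "profile_vs_compounds"),
                 r_pls = c(res$pls_classes$r_pls, res$pls_compounds$r_pls),
                 p_value = c(res$pls_classes$p_value, res$pls_compounds$p_value),
                 n_perm = res$config$n_perm),
      "pls_summary.tsv")
  tsv(data.frame(species = res$pls_compounds$species,
                 score_profile = res$pls_compounds$left_scores,
                 score_compounds = res$pls_compounds$right_scores),
      "pls_scores.tsv")
  tsv(res$pgls$table, "anova_type3.tsv")
  co <- res$pgls$fit$coefficients
  tsv(data.frame(coefficient = rownames(co), as.data.frame(co),
                 check.names = FALSE), "pgls_coefficients.tsv")
  for (tm in names(res$pgls$regions)) {
    tsv(res$pgls$regions[[tm]], paste0("regions_", tm, ".tsv"))
    pr <- res$pgls$predictions[[tm]]
    tsv(data.frame(bin = seq_len(ncol(pr)), pred_lo = pr[1L, ],
                   pred_hi = pr[2L, ]),
        paste0("prediction_", tm, ".tsv"))
  }
  tsv(data.frame(model = c("R_P~R_L", "H_P~H_L"),
                 slope = c(res$complexity$richness$slope,
                           res$complexity$entropy$slope),
                 pseudo_F = c(res$complexity$richness$anova$table$pseudo_F,
                              res$complexity$entropy$anova$table$pseudo_F),
                 p_perm = c(res$complexity$richness$anova$table$p_perm,
                            res$complexity$entropy$anova$table$p_perm)),
      "complexity_regressions.tsv")
  manifest <- res$config
  manifest$flagged <- as.list(res$pgls$flagged)
  if (!is.null(ds$paths)) {
    manifest$input_md5 <- as.list(tools::md5sum(unlist(ds$paths)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Jaccard overlap between two bin sets
#'
#' Used to score recovery of injected responsive bins.
#'
#' @param a,b Integer vectors of bin indices.
#' @return `|a n b| / |a u b|` (0 when both empty).
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Bins covered by a region report
#' @param regions data.frame from [responsive_regions()].
#' @return Integer vector of all bins inside the reported regions.
#' @export
region_bins <- function(regions) {
  if (!nrow(regions)) return(integer(0))
  unlist(lapply(seq_len(nrow(regions)), function(i)
    regions$start_bin[i]:regions$end_bin[i]))
}
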