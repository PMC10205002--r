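#' Normalize a raw electrophoretic profile
#'
#' An electrophoretogram (EPG) is a one-dimensional profile of relative
#' protein abundance across molecular-weight bins (300 bins in the study
#' data). Normalization divides by the total so the profile sums to one.
#'
#' @param raw Nonnegative numeric vector, not all zero.
#' @param n_bins Expected length; `NULL` skips the length check.
#' @return Numeric vector summing to 1.
#' @export
normalize_profile <- function(raw, n_bins = NULL) {
  raw <- as.numeric(raw)
  if (!is.null(n_bins) && length(raw) != n_bins) {
    stop_glandcov("profile", "profile has length ", length(raw),
                  ", expected ", n_bins)
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop_glandcov("profile", "profile entries must be finite and nonnegative")
  }
  s <- sum(raw)
  if (s <= 0) stop_glandcov("profile", "all-zero profile")
  raw / s
}

#' Shannon entropy of a normalized profile (nats)
#'
#' `H = -sum(p * ln p)` with the convention `0 * ln 0 = 0`. Used as the
#' complexity index for both protein profiles (H_P) and lipid profiles
#' (H_L): zero for a single-band profile, `ln(n)` for a perfectly even one.
#'
#' @param p Normalized nonnegative vector (sums to 1).
#' @return Nonnegative entropy in nats.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop_glandcov("profile", "negative entries")
  if (abs(sum(p) - 1) > 1e-6) {
    stop_glandcov("profile", "profile must be normalized (sum = 1); got sum ",
                  format(sum(p)))
  }
  pp <- p[p > 0]
  -sum(pp * log(pp))
}

#' Windowed local-maxima peak detection
#'
#' A bin is a candidate peak when it is strictly higher than every other
#' bin inside a centered window of odd width `window` (truncated at the
#' profile ends; the first and last bins are never peaks). Candidates are
#' retained when they reach at least `rel_height` of the tallest candidate.
#' The retained count is the peak richness R_P of the profile.
#'
#' @param p Normalized profile.
#' @param window Odd integer >= 3 (default 3, the study setting).
#' @param rel_height Fraction of the tallest detected peak (default 0.10).
#' @return List with `count` (integer) and `indices` (1-based bin indices).
#' @export
detect_peaks <- function(p, window = 3L, rel_height = 0.10) {
  p <- as.numeric(p)
  n <- length(p)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop_glandcov("profile", "window must be an odd integer >= 3")
  }
  if (rel_height <= 0 || rel_height >= 1) {
    stop_glandcov("profile", "rel_height must be in (0, 1)")
  }
  half <- (window - 1L) %/% 2L
  cand <- integer(0)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      nb <- p[setdiff(lo:hi, i)]
      if (all(p[i] > nb)) cand <- c(cand, i)
    }
  }
  if (!length(cand)) return(list(count = 0L, indices = integer(0)))
  keep <- cand[p[cand] >= rel_height * max(p[cand])]
  list(count = length(keep), indices = keep)
}

#' Lipid richness: number of distinct compounds present
#'
#' @param abund Nonnegative abundance vector for one species.
#' @return Integer count of strictly positive entries.
#' @export
lipid_richness <- function(abund) {
  abund <- as.numeric(abund)
  if (any(abund < 0)) stop_glandcov("profile", "negative abundances")
  sum(abund > 0)
}

#' Log-linear bin-to-kDa calibration
#'
#' Electrophoretic migration is approximately linear in log molecular
#' weight, so the default synthetic calibration maps bins to kDa
#' log-linearly from the heaviest to the lightest bin. Supply a measured
#' two-column (bin, kDa) calibration instead whenever one exists.
#'
#' @param n_bins Number of profile bins.
#' @param kda_max,kda_min kDa of the first and last bin.
#' @return Numeric vector of length `n_bins`, decreasing.
#' @export
kda_calibration <- function(n_bins, kda_max = 250, kda_min = 10) {
  exp(seq(log(kda_max), log(kda_min), length.out = n_bins))
}

#' Per-species complexity table from profile and compound matrices
#'
#' Computes peak richness and Shannon entropy for each EPG row, and
#' richness plus entropy of the closed compound abundances, mirroring the
#' four complexity scalars (R_P, H_P, R_L, H_L) used in the univariate
#' regressions.
#'
#' @param epg Species x bins matrix of normalized profiles.
#' @param compounds Species x compounds matrix of nonnegative abundances.
#' @param window,rel_height Passed to [detect_peaks()].
#' @return data.frame with columns species, R_P, H_P, R_L, H_L.
#' @export
complexity_table <- function(epg, compounds, window = 3L, rel_height = 0.10) {
  epg <- as.matrix(epg)
  compounds <- as.matrix(compounds)
  stopifnot(nrow(epg) == nrow(compounds))
  sp <- rownames(epg)
  if (is.null(sp)) sp <- paste0("sp", seq_len(nrow(epg)))
  data.frame(
    species = sp,
    R_P = vapply(seq_len(nrow(epg)), function(i)
      detect_peaks(epg[i, ], window, rel_height)$count, integer(1)),
    H_P = vapply(seq_len(nrow(epg)), function(i)
      shannon_entropy(normalize_profile(epg[i, ])), numeric(1)),
    R_L = vapply(seq_len(nrow(compounds)), function(i)
      lipid_richness(compounds[i, ]), numeric(1)),
    H_L = vapply(seq_len(nrow(compounds)), function(i)
      shannon_entropy(closure(compounds[i, ])), numeric(1)),
    row.names = NULL
  )
}
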