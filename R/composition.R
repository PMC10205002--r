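#' Closure of a nonnegative vector to a composition
#'
#' Divides each entry by the vector total so parts sum to one.
#'
#' @param x Nonnegative numeric vector with at least one positive entry.
#' @return Numeric vector summing to 1.
#' @export
closure <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_glandcov("composition", "non-finite entries")
  if (any(x < 0)) stop_glandcov("composition", "negative entries")
  s <- sum(x)
  if (s <= 0) stop_glandcov("composition", "all-zero vector cannot be closed")
  x / s
}

#' Row-wise closure of a matrix
#' @param X Matrix of nonnegative rows.
#' @return Matrix with each row summing to 1.
#' @export
closure_rows <- function(X) {
  X <- as.matrix(X)
  out <- t(apply(X, 1L, closure))
  dimnames(out) <- dimnames(X)
  out
}

#' Multiplicative simple zero replacement
#'
#' CLR needs strictly positive parts. Zeros in each (closed) row are set to
#' `delta` and the positive entries are rescaled by `1 - k * delta` (k the
#' number of zeros in that row), so rows still sum to one and ratios among
#' the nonzero parts are preserved.
#'
#' @param X Matrix whose rows are closed compositions.
#' @param delta Positive replacement value, or `"auto"` for half the
#'   smallest positive entry in the whole matrix.
#' @return Matrix of strictly positive rows summing to 1.
#' @export
replace_zeros <- function(X, delta = "auto") {
  X <- as.matrix(X)
  if (any(X < 0)) stop_glandcov("composition", "negative entries")
  pos <- X[X > 0]
  if (!length(pos)) stop_glandcov("composition", "matrix has no positive entries")
  if (identical(delta, "auto")) delta <- 0.5 * min(pos)
  delta <- as.numeric(delta)
  if (delta <= 0) stop_glandcov("composition", "delta must be positive")
  if (delta >= min(pos)) {
    stop_glandcov("composition", "delta (", format(delta),
                  ") must be smaller than the smallest positive entry (",
                  format(min(pos)), ")")
  }
  out <- t(apply(X, 1L, function(row) {
    k <- sum(row == 0)
    if (k == 0L) return(row)
    row[row > 0] <- row[row > 0] * (1 - k * delta)
    row[row == 0] <- delta
    row
  }))
  dimnames(out) <- dimnames(X)
  out
}

#' Centred-log-ratio transform
#'
#' `z_ij = ln(x_ij / g_i)` with `g_i` the geometric mean of row i. Maps
#' each compositional row to a zero-sum vector in real space; natural log
#' throughout.
#'
#' @param X Matrix with strictly positive entries (run [replace_zeros()]
#'   first if needed).
#' @return Matrix of the same shape; every row sums to 0.
#' @export
clr <- function(X) {
  X <- as.matrix(X)
  if (any(X <= 0)) {
    stop_glandcov("composition",
                  "clr requires strictly positive entries; use replace_zeros()")
  }
  lx <- log(X)
  sweep(lx, 1L, rowMeans(lx), "-")
}

#' Inverse centred-log-ratio transform
#'
#' Row-wise closure of `exp(Z)`; the row maximum is subtracted before
#' exponentiation so extreme values cannot overflow. Inverts [clr()] on
#' closed positive matrices.
#'
#' @param Z Matrix of finite reals.
#' @return Matrix of compositions (rows sum to 1).
#' @export
clr_inverse <- function(Z) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop_glandcov("composition", "non-finite entries")
  out <- t(apply(Z, 1L, function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  }))
  dimnames(out) <- dimnames(Z)
  out
}
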