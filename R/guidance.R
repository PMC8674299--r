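#' Minimum l2-norm least-squares solution (guidance vector)
#'
#' Computes the shortest (minimum Euclidean norm) least-squares solution
#' \eqn{\hat\gamma = X^+ y} of the linear system \eqn{y = X\gamma}, where
#' \eqn{X^+} is the Moore--Penrose pseudoinverse.  For an underdetermined
#' system (more columns than rows) with full row rank this is the unique
#' solution of minimum norm satisfying \eqn{X\hat\gamma = y}; in general it is
#' the least-squares solution of minimum norm.  The decimation solvers use
#' this vector as a guide: its largest-magnitude entry points at a predictor
#' that is likely to carry a truly nonzero coefficient.
#'
#' The production route solves the n-by-n normal system \eqn{(X X^\top) z = y}
#' through a symmetric eigendecomposition of the Gram matrix and returns
#' \eqn{\hat\gamma = X^\top z}, using the identity \eqn{X^+ = X^\top (X
#' X^\top)^+}.  Eigenvalues whose square roots fall below \code{rank_tol}
#' times the largest singular value are treated as exact zeros, as are
#' eigenvalues below the numerical noise floor of the Gram computation
#' (\code{max(n,m) * .Machine$double.eps} relative); directions belonging to
#' the (numerical) null space contribute nothing.  A precomputed Gram matrix
#' can be supplied to avoid the \eqn{O(n^2 m)} product when the caller
#' maintains it incrementally.
#'
#' @param X numeric matrix, n rows (samples) by m columns (active predictors).
#' @param y numeric response vector of length n.
#' @param rank_tol relative singular-value cutoff; singular values below
#'   \code{rank_tol} times the largest are treated as zero.  Default
#'   \code{max(dim(X)) * .Machine$double.eps}, the standard pseudoinverse
#'   cutoff.
#' @param index_map integer vector mapping column positions of \code{X} to
#'   original predictor indices (defaults to \code{1:m}); carried through so
#'   that pivot selection can report original indices after decimation.
#' @param gram optional precomputed \code{tcrossprod(X)} (n-by-n).
#'
#' @return An object of class \code{"assd_guidance"}: a list with
#'   \code{values} (the guidance vector, length m), \code{rank_used} (number
#'   of singular values treated as nonzero) and \code{index_map}.
#'
#' @examples
#' X <- rbind(c(1, 0, 0), c(0, 1, 0))
#' min_norm_ls(X, c(2, 3))$values   # (2, 3, 0): the third entry costs norm
#'
#' @seealso [select_pivot()], [run_decimation()]
#' @export
min_norm_ls <- function(X, y, rank_tol = NULL, index_map = NULL, gram = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  m <- ncol(X)
  if (n < 1L || m < 1L)
    stop("X must have at least one row and one column")
  if (length(y) != n)
    stop(sprintf("dimension mismatch: X has %d rows but y has length %d",
                 n, length(y)))
  if (all(X == 0))
    stop("degenerate design: X is all zero")
  if (is.null(index_map)) index_map <- seq_len(m)
  if (length(index_map) != m)
    stop("index_map length must equal ncol(X)")
  if (is.null(rank_tol)) rank_tol <- max(n, m) * .Machine$double.eps

  if (is.null(gram)) gram <- tcrossprod(X)
  ev <- eigen(gram, symmetric = TRUE)
  emax <- ev$values[1L]
  if (emax <= 0) stop("degenerate design: Gram matrix has no positive eigenvalue")
  # two cutoffs: the requested singular-value cutoff, and the noise floor of
  # forming X X^T in floating point (eigenvalues below it are pure round-off)
  sv_keep <- sqrt(pmax(ev$values, 0)) > rank_tol * sqrt(emax)
  floor_keep <- ev$values > max(n, m) * .Machine$double.eps * emax
  keep <- sv_keep & floor_keep
  r <- sum(keep)
  if (r == 0L) stop("degenerate design: numerical rank zero")
  U <- ev$vectors[, keep, drop = FALSE]
  z <- U %*% (crossprod(U, y) / ev$values[keep])
  g <- as.numeric(crossprod(X, z))
  structure(list(values = g, rank_used = r, index_map = as.integer(index_map)),
            class = "assd_guidance")
}

#' @export
print.assd_guidance <- function(x, ...) {
  cat(sprintf("Guidance vector: %d active columns, numerical rank %d\n",
              length(x$values), x$rank_used))
  cat("largest |entries|:\n")
  o <- order(abs(x$values), decreasing = TRUE)[seq_len(min(5L, length(x$values)))]
  print(data.frame(index = x$index_map[o], value = x$values[o]))
  invisible(x)
}

#' Select the decimation pivot from a guidance vector
#'
#' Returns the original column index of the guidance-vector entry with the
#' largest absolute value.  Ties are broken toward the smallest original
#' index, so selection is deterministic across platforms.
#'
#' @param g an \code{"assd_guidance"} object from [min_norm_ls()].
#' @param candidates optional logical mask (length of \code{g$values}); only
#'   positions marked \code{TRUE} compete.  Used by the decimation loop to
#'   exclude columns annihilated by earlier projections.
#' @return integer, an original predictor index in 1..p.
#' @export
select_pivot <- function(g, candidates = NULL) {
  stopifnot(inherits(g, "assd_guidance"))
  v <- abs(g$values)
  if (length(v) == 0L) stop("empty guidance vector")
  if (!is.null(candidates)) {
    stopifnot(length(candidates) == length(v))
    v[!candidates] <- -Inf
  }
  mx <- max(v)
  if (!is.finite(mx) || mx == 0)
    stop("uninformative guidance: all candidate entries are zero")
  at <- which(v == mx)
  # resolve ties by the smallest *original* index
  k <- at[which.min(g$index_map[at])]
  as.integer(g$index_map[k])
}

#' Proportion of true nonzeros among the top-ranked guidance entries
#'
#' For each r = 1..p, ranks the guidance entries by absolute value
#' (descending, ties to the smaller original index) and reports the
#' proportion q(r) of the r top-ranked original indices whose true
#' coefficient is nonzero.  A guidance vector that concentrates the true
#' support in its head has q(r) near 1 for r up to s0.
#'
#' @param g an \code{"assd_guidance"} object over all p predictors.
#' @param beta0 true coefficient vector of length p.
#' @return numeric vector \code{q} of length p with \code{q[r]} in [0, 1].
#' @export
rank_curve <- function(g, beta0) {
  stopifnot(inherits(g, "assd_guidance"))
  p <- length(g$values)
  if (length(beta0) != p)
    stop(sprintf("length mismatch: guidance has %d entries, beta0 has %d",
                 p, length(beta0)))
  o <- order(-abs(g$values), g$index_map)
  hits <- beta0[g$index_map[o]] != 0
  cumsum(hits) / seq_len(p)
}
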