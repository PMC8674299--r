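#' Stopping policy for the decimation loop
#'
#' Bundles the termination rule used by [run_decimation()].  Three modes are
#' supported: \code{"assd"} and \code{"ssd1"} stop once the Euclidean norm of
#' the residual response drops to \code{eta} or after \code{L_max} steps,
#' whichever comes first (the adaptive early-stopping rule); \code{"ssd_naive"}
#' is the original noise-free criterion, stopping when the mean absolute
#' residual \eqn{\|y'\|_1 / n} falls below \code{naive_tol} or when no
#' candidate column remains.
#'
#' The defaults are the ones used throughout the simulation study:
#' \code{L_max = floor(n / log(n))} (consistent support recovery is impossible
#' beyond order n/log(n) nonzeros, so there is no point decimating further)
#' and \code{eta = sqrt(n) * sigma} when the noise s.d. \eqn{\sigma} is known
#' (the expected residual norm once the true support is captured), else the
#' small fallback 0.1.
#'
#' @param mode one of \code{"assd"}, \code{"ssd1"}, \code{"ssd_naive"}.
#' @param n sample count, used for the \code{eta}/\code{L_max} defaults.
#' @param sigma known noise standard deviation, or \code{NULL}.
#' @param eta residual l2-norm threshold; default \code{sqrt(n)*sigma} or 0.1.
#' @param L_max maximum number of decimation steps; default
#'   \code{floor(n/log(n))}.  Ignored by \code{"ssd_naive"}.
#' @param naive_tol threshold on \eqn{\|y'\|_1/n} for \code{"ssd_naive"};
#'   default \code{1e-5}.
#' @return a list of class \code{"assd_policy"}.
#' @export
stopping_policy <- function(mode = c("assd", "ssd1", "ssd_naive"),
                            n = NULL, sigma = NULL,
                            eta = NULL, L_max = NULL, naive_tol = 1e-5) {
  mode <- match.arg(mode)
  if (is.null(L_max)) {
    if (is.null(n)) stop("either n or L_max must be given")
    L_max <- max(1L, floor(n / log(n)))
  }
  if (is.null(eta)) {
    eta <- if (!is.null(sigma)) sqrt(n) * sigma else 0.1
  }
  if (eta < 0) stop("eta must be nonnegative")
  if (L_max < 1) stop("L_max must be at least 1")
  if (naive_tol <= 0) stop("naive_tol must be positive")
  structure(list(mode = mode, eta = eta, L_max = as.integer(L_max),
                 naive_tol = naive_tol),
            class = "assd_policy")
}

new_decimation_state <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  list(X_active = X,
       y_resid = y,
       index_map = seq_len(ncol(X)),
       records = list(),
       step_count = 0L,
       resid_norms = norm2(y),
       stop_reason = NA_character_)
}

norm2 <- function(v) sqrt(sum(v * v))

#' One decimation step
#'
#' Projects the pivot column out of the system: every remaining active column
#' is replaced by its component orthogonal to the pivot,
#' \eqn{X_i' = X_i - (X_i^\top X_k / X_k^\top X_k) X_k}, the residual response
#' by \eqn{y' = y - (y^\top X_k / X_k^\top X_k) X_k}, and the pivot column is
#' removed.  The scalar projection coefficients are recorded so that the
#' selected coefficients can later be recovered by back-substitution
#' ([backtrack()]).
#'
#' @param state a decimation state (list with \code{X_active}, \code{y_resid},
#'   \code{index_map}, \code{records}, \code{step_count}, \code{resid_norms}).
#' @param k original column index of the pivot (must be active).
#' @param rank_tol relative tolerance below which the pivot column norm is
#'   considered zero.
#' @return the updated state, with one more \code{ProjectionRecord}-style
#'   entry in \code{records}: a list with \code{pivot}, \code{scale}
#'   (\eqn{\|X_k\|^2} in the decimated frame), \code{response_coef}
#'   (\eqn{y^\top X_k/\|X_k\|^2}) and \code{cross_coefs} (named vector of
#'   \eqn{X_i^\top X_k/\|X_k\|^2} over the other active original indices).
#' @export
decimate_step <- function(state, k, rank_tol = NULL) {
  pos <- match(k, state$index_map)
  if (is.na(pos)) stop(sprintf("pivot %d is not an active column", k))
  Xk <- state$X_active[, pos]
  nrm2 <- sum(Xk * Xk)
  if (is.null(rank_tol)) rank_tol <- max(dim(state$X_active)) * .Machine$double.eps
  if (nrm2 <= .Machine$double.xmin ||
      nrm2 <= rank_tol^2 * max(colSums(state$X_active^2)))
    stop(sprintf("zero pivot column: column %d has negligible norm", k))

  proj <- as.numeric(crossprod(state$X_active, Xk)) / nrm2   # length m
  ycoef <- sum(state$y_resid * Xk) / nrm2

  keep <- seq_along(state$index_map)[-pos]
  cross <- proj[keep]
  names(cross) <- as.character(state$index_map[keep])

  rec <- list(pivot = as.integer(k), scale = nrm2,
              response_coef = ycoef, cross_coefs = cross)

  X_new <- state$X_active[, keep, drop = FALSE] -
    outer(Xk, proj[keep])
  y_new <- state$y_resid - ycoef * Xk

  state$X_active <- X_new
  state$y_resid <- y_new
  state$index_map <- state$index_map[keep]
  state$records[[length(state$records) + 1L]] <- rec
  state$step_count <- state$step_count + 1L
  state$resid_norms <- c(state$resid_norms, norm2(y_new))
  state
}

policy_satisfied <- function(policy, y_resid) {
  n <- length(y_resid)
  switch(policy$mode,
         assd = ,
         ssd1 = norm2(y_resid) <= policy$eta,
         ssd_naive = sum(abs(y_resid)) / n < policy$naive_tol)
}

#' Run shortest-solution guided decimation
#'
#' Iterates \{guidance vector on the current decimated system, pivot
#' selection, projection step\} until the stopping policy fires.  Columns
#' whose decimated norm falls below a small relative tolerance are removed
#' from pivot candidacy (they have been annihilated by earlier projections
#' and carry no information); if no candidate remains, or the guidance vector
#' is numerically zero, the loop stops with reason \code{"exhausted"}.
#'
#' The Gram matrix of the rows is maintained incrementally: projecting the
#' normalized pivot w out of X maps the Gram matrix G = X X^T to
#' (I - w w^T) G (I - w w^T), a rank-2 symmetric update costing O(n^2) per
#' step, so each guidance solve needs only an n-by-n eigendecomposition
#' rather than a fresh O(n^2 m) product.
#'
#' @param X n-by-p design matrix.
#' @param y response vector of length n.
#' @param policy an \code{"assd_policy"} from [stopping_policy()].
#' @param rank_tol relative singular-value cutoff for the guidance solves
#'   (default \code{max(n,p) * .Machine$double.eps}).
#' @param verbose if \code{TRUE}, prints one line per step (step, pivot,
#'   |guidance| at the pivot, residual l2-norm).
#' @return the final decimation state; a list with the decimated matrix,
#'   residual \code{y_resid}, \code{index_map}, the ordered projection
#'   \code{records}, \code{step_count}, the trace \code{resid_norms}
#'   (length step_count + 1, starting at \eqn{\|y\|_2}) and
#'   \code{stop_reason} (one of \code{"criterion"}, \code{"L_max"},
#'   \code{"exhausted"}).
#' @export
run_decimation <- function(X, y, policy, rank_tol = NULL, verbose = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 1L || p < 1L) stop("X must be a nonempty matrix")
  if (length(y) != n) stop("dimension mismatch between X and y")
  if (is.null(rank_tol)) rank_tol <- max(n, p) * .Machine$double.eps

  state <- new_decimation_state(X, y)
  if (policy_satisfied(policy, state$y_resid)) {
    state$stop_reason <- "criterion"
    return(state)
  }

  gram <- tcrossprod(state$X_active)
  # deactivate columns once their decimated norm drops below ~sqrt(n*eps)
  # relative to their original norm (annihilated by earlier projections)
  orig_norm2 <- colSums(state$X_active^2)
  cur_norm2 <- orig_norm2
  deact_rel2 <- n * .Machine$double.eps        # on squared norms
  candidates <- orig_norm2 > 0

  max_steps <- if (policy$mode == "ssd_naive") p else min(policy$L_max, p)

  repeat {
    if (state$step_count >= max_steps) {
      state$stop_reason <- if (policy$mode == "ssd_naive") "exhausted" else "L_max"
      break
    }
    if (!any(candidates)) {
      state$stop_reason <- "exhausted"
      break
    }
    g <- tryCatch(
      min_norm_ls(state$X_active, state$y_resid, rank_tol = rank_tol,
                  index_map = state$index_map, gram = gram),
      error = function(e) e)
    if (inherits(g, "error")) {
      state$stop_reason <- "exhausted"
      break
    }
    k <- tryCatch(select_pivot(g, candidates = candidates),
                  error = function(e) e)
    if (inherits(k, "error")) {
      state$stop_reason <- "exhausted"
      break
    }

    pos <- match(k, state$index_map)
    Xk <- state$X_active[, pos]
    wnrm <- norm2(Xk)
    w <- Xk / wnrm

    if (verbose)
      message(sprintf("step %d: pivot %d |gamma|=%.4g resid=%.6g",
                      state$step_count + 1L, k, abs(g$values[pos]),
                      utils::tail(state$resid_norms, 1L)))

    state <- decimate_step(state, k, rank_tol = rank_tol)

    # rank-2 symmetric Gram update: G <- (I - w w^T) G (I - w w^T)
    gw <- as.numeric(gram %*% w)
    a <- sum(w * gw)
    gram <- gram - tcrossprod(w, gw) - tcrossprod(gw, w) + a * tcrossprod(w)
    gram <- (gram + t(gram)) / 2

    cur_norm2 <- colSums(state$X_active^2)
    orig_norm2 <- orig_norm2[-pos]
    candidates <- cur_norm2 > deact_rel2 * orig_norm2 & orig_norm2 > 0

    if (policy_satisfied(policy, state$y_resid)) {
      state$stop_reason <- "criterion"
      break
    }
  }
  state
}

#' Back-substitute the decimation records into a coefficient vector
#'
#' During decimation, selecting pivot k at step t fixes the one-variable
#' least-squares relation \eqn{\beta_k = y^\top X_k/\|X_k\|^2 - \sum_{i\ne k}
#' (X_i^\top X_k/\|X_k\|^2)\beta_i} in the frame of step t.  With all
#' unselected coefficients set to zero, these L relations are triangular in
#' reverse selection order and are solved by a single backward sweep.  The
#' result equals the ordinary least-squares fit of y on the selected columns
#' (the decimation is a Gram--Schmidt orthogonalization).
#'
#' @param records list of projection records from [run_decimation()].
#' @param p total number of predictors.
#' @return numeric coefficient vector of length p, zero off the selected set.
#' @export
backtrack <- function(records, p) {
  beta <- numeric(p)
  L <- length(records)
  if (L == 0L) return(beta)
  pivots <- vapply(records, function(r) r$pivot, integer(1))
  if (anyDuplicated(pivots))
    stop("duplicate pivot in decimation records")
  for (t in rev(seq_len(L))) {
    rec <- records[[t]]
    later <- if (t < L) pivots[(t + 1L):L] else integer(0)
    val <- rec$response_coef
    if (length(later)) {
      cc <- rec$cross_coefs[as.character(later)]
      val <- val - sum(cc * beta[later])
    }
    beta[rec$pivot] <- val
  }
  beta
}
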