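#' Empirical coefficient-uncertainty scale
#'
#' Sorts the L selected coefficients by absolute value (ascending) and uses
#' the signed values of the smaller half, \eqn{\beta_{r_1}, \ldots,
#' \beta_{r_{\lfloor L/2\rfloor}}}, to form
#' \deqn{\hat\sigma = \sqrt{ (2/L) \sum_j (\beta_{r_j} - m)^2 },}
#' with m their mean (also computed with the 2/L factor).  This measures the
#' spread of the least-certain coefficient estimates; it is distinct from the
#' noise s.d. of the regression model itself.
#'
#' @param selected_betas numeric vector of the L coefficient values assigned
#'   during decimation (nonzero entries of the backtracked solution).
#' @return scalar \eqn{\hat\sigma \ge 0}.
#' @export
sigma_hat <- function(selected_betas) {
  L <- length(selected_betas)
  if (L < 2L)
    stop("too few coefficients for uncertainty estimate (need at least 2)")
  o <- order(abs(selected_betas))
  half <- selected_betas[o][seq_len(L %/% 2L)]
  m <- (2 / L) * sum(half)
  sqrt((2 / L) * sum((half - m)^2))
}

#' Basic hard-thresholding level
#'
#' The universal-threshold scale \eqn{\theta_0 = \hat\sigma \sqrt{2 \ln p}},
#' from which actual thresholds are formed as integer multiples
#' \eqn{\theta = \tau \theta_0}.
#'
#' @param sigma_hat nonnegative coefficient-uncertainty scale.
#' @param p number of predictors (at least 2).
#' @return scalar \eqn{\theta_0 \ge 0}.
#' @export
base_threshold <- function(sigma_hat, p) {
  if (p < 2) stop("p must be at least 2")
  if (sigma_hat < 0) stop("sigma_hat must be nonnegative")
  sigma_hat * sqrt(2 * log(p))
}

#' Restricted least-squares refit
#'
#' Least-squares fit of y on the columns in \code{support}, zeros elsewhere;
#' the minimum-norm solution is returned if the restricted system is
#' rank-deficient.  An empty support yields the zero vector.
#'
#' @param X n-by-p design matrix.
#' @param y response vector.
#' @param support integer vector of retained column indices.
#' @param rank_tol relative singular-value cutoff for rank decisions.
#' @return coefficient vector of length p.
#' @export
refit_restricted <- function(X, y, support, rank_tol = NULL) {
  p <- ncol(X)
  beta <- numeric(p)
  support <- sort(unique(as.integer(support)))
  if (length(support) == 0L) return(beta)
  if (any(support < 1L | support > p)) stop("support indices out of range")
  Xs <- X[, support, drop = FALSE]
  qr_fit <- qr(Xs)
  if (qr_fit$rank == ncol(Xs)) {
    beta[support] <- qr.coef(qr_fit, y)
  } else {
    # rank-deficient restricted system: minimum-norm LS via SVD pseudoinverse
    sv <- svd(Xs)
    tol <- if (is.null(rank_tol)) max(dim(Xs)) * .Machine$double.eps else rank_tol
    keep <- sv$d > tol * sv$d[1L]
    beta[support] <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep])
  }
  beta
}

#' BIC score of a restricted fit
#'
#' \deqn{\mathrm{BIC} = \tfrac12 \|r\|_2^2 + p_{nz} \ln n,} trading squared
#' prediction error against the size of the retained support.
#'
#' @param residual residual vector of the restricted fit.
#' @param p_nz number of retained (nonzero) coefficients.
#' @param n sample count (at least 2).
#' @return scalar BIC value.
#' @export
bic_score <- function(residual, p_nz, n) {
  if (n < 2) stop("n must be at least 2")
  0.5 * sum(residual^2) + p_nz * log(n)
}

#' BIC-guided hard-thresholding scan
#'
#' Second-stage refinement of a decimation solution.  From the L nonzero
#' entries of \code{beta_init} it computes the uncertainty scale
#' \eqn{\hat\sigma} ([sigma_hat()]) and the base level \eqn{\theta_0}
#' ([base_threshold()]).  The multiplier \eqn{\tau} then sweeps a grid from 0
#' to R: at each \eqn{\tau}, indices whose current coefficient magnitude falls
#' below \eqn{\tau\theta_0} are added (cumulatively) to the exclusion set, the
#' remaining coefficients are refit by restricted least squares
#' ([refit_restricted()]), and the fit is scored by [bic_score()] with
#' \eqn{p_{nz}} the retained-support size.  The coefficient vector at the
#' BIC-minimizing \eqn{\tau} is returned (ties resolved toward the largest
#' \eqn{\tau}, i.e. the sparsest model).
#'
#' By default the magnitudes compared against \eqn{\tau\theta_0} are the
#' current refit coefficients (each scan step is self-consistent);
#' \code{compare = "initial"} freezes the comparison at the decimation values
#' for sensitivity checks.
#'
#' If \eqn{\theta_0 = 0} (all lower-half coefficients identical) or fewer than
#' two coefficients were selected, no thresholding is possible and the scan
#' degenerates to the \eqn{\tau = 0} refit; this is recorded in the result,
#' not an error.
#'
#' @param X n-by-p design matrix.
#' @param y response vector.
#' @param beta_init coefficient vector from [backtrack()].
#' @param R largest threshold multiplier (default 20).
#' @param tau_step grid step for the multiplier (default 0.1).  The step must
#'   be fine enough that some \eqn{\tau\theta_0} lands between the spurious
#'   coefficient magnitudes and the smallest true one; a unit step frequently
#'   overshoots that gap, in which case no pruning survives the BIC
#'   comparison.
#' @param compare \code{"refit"} (default) or \code{"initial"}.
#' @param rank_tol relative singular-value cutoff passed to the refits.
#' @return a list of class \code{"assd_scan"}: \code{tau_grid},
#'   \code{bic_trace}, \code{support_trace} (retained-support size per tau),
#'   \code{chosen_tau}, \code{beta_final}, \code{sigma_hat}, \code{theta0},
#'   \code{degenerate} (logical).
#' @export
threshold_scan <- function(X, y, beta_init, R = 20, tau_step = 0.1,
                           compare = c("refit", "initial"), rank_tol = NULL) {
  compare <- match.arg(compare)
  if (R < 0) stop("R must be nonnegative")
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(beta_init) != p) stop("beta_init length must equal ncol(X)")

  support0 <- which(beta_init != 0)
  L <- length(support0)
  sh <- if (L >= 2L) sigma_hat(beta_init[support0]) else 0
  th0 <- if (p >= 2L) base_threshold(sh, p) else 0
  degenerate <- (th0 == 0)

  tau_grid <- if (degenerate) 0 else seq(0, R, by = tau_step)

  retained <- support0
  bic_trace <- numeric(length(tau_grid))
  support_trace <- integer(length(tau_grid))
  betas <- vector("list", length(tau_grid))
  beta_cur <- beta_init

  for (j in seq_along(tau_grid)) {
    tau <- tau_grid[j]
    cmp_beta <- if (compare == "refit") beta_cur else beta_init
    drop_idx <- retained[abs(cmp_beta[retained]) < tau * th0]
    retained <- setdiff(retained, drop_idx)
    beta_cur <- refit_restricted(X, y, retained, rank_tol = rank_tol)
    resid <- y - as.numeric(X %*% beta_cur)
    support_trace[j] <- length(retained)
    bic_trace[j] <- bic_score(resid, length(retained), n)
    betas[[j]] <- beta_cur
  }

  best <- max(which(bic_trace == min(bic_trace)))   # sparsest among ties
  structure(list(tau_grid = tau_grid,
                 bic_trace = bic_trace,
                 support_trace = support_trace,
                 chosen_tau = tau_grid[best],
                 beta_final = betas[[best]],
                 sigma_hat = sh,
                 theta0 = th0,
                 degenerate = degenerate),
            class = "assd_scan")
}
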