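# Independent oracles, deliberately separate from the production solve paths.

# Moore-Penrose pseudoinverse solution via a full SVD of X itself
# (the production route goes through the Gram matrix of the rows).
pinv_oracle <- function(X, y, tol = NULL) {
  sv <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * .Machine$double.eps
  keep <- sv$d > tol * sv$d[1L]
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
}

# OLS on a fixed support via the normal equations.
ols_oracle <- function(X, y, support) {
  Xs <- X[, support, drop = FALSE]
  beta <- numeric(ncol(X))
  beta[support] <- solve(crossprod(Xs), crossprod(Xs, y))
  beta
}

rel_err <- function(a, b) {
  d <- sqrt(sum((a - b)^2))
  s <- sqrt(sum(b^2))
  if (s == 0) d else d / s
}

# small sparse-regression instance used across tests
make_instance <- function(n, p, s0, sigma = 0, seed = 1,
                          law = c("pos", "signed")) {
  law <- match.arg(law)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta0 <- numeric(p)
  supp <- sort(sample.int(p, s0))
  vals <- runif(s0, 0.5, 1)
  if (law == "signed") vals <- vals * sample(c(-1, 1), s0, replace = TRUE)
  beta0[supp] <- vals
  y <- drop(X %*% beta0) + if (sigma > 0) rnorm(n, 0, sigma) else 0
  list(X = X, y = y, beta0 = beta0, support = supp)
}
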