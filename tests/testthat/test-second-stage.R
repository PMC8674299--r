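test_that("uncertainty scale matches hand evaluation", {
  # identical lower-half values give zero spread
  expect_equal(sigma_hat(c(0.2, 0.2, 5, -7)), 0)
  # lower-half pair {0.1, 0.3}: m = 0.2, sigma_hat = sqrt(0.5*(0.01+0.01)) = 0.1
  expect_equal(sigma_hat(c(0.1, 0.3, 2, -3)), 0.1, tolerance = 1e-12)
  # homogeneity: scaling inputs scales the estimate
  x <- c(0.3, -0.7, 1.2, 0.05, 2)
  expect_equal(sigma_hat(3 * x), 3 * sigma_hat(x), tolerance = 1e-12)
  expect_equal(sigma_hat(-3 * x), 3 * sigma_hat(x), tolerance = 1e-12)
  expect_error(sigma_hat(0.5), "too few")
})

test_that("base threshold follows the universal-threshold formula", {
  expect_equal(base_threshold(0, 100), 0)
  expect_equal(base_threshold(1, exp(2)), 2, tolerance = 1e-12)
  expect_equal(base_threshold(0.5, 1000), 0.5 * sqrt(2 * log(1000)),
               tolerance = 1e-12)
  expect_equal(base_threshold(0.5, 1000), 1.8585, tolerance = 1e-4)
  expect_error(base_threshold(1, 1), "at least 2")
})

test_that("restricted refit matches the normal-equations oracle", {
  set.seed(9)
  for (i in 1:10) {
    X <- matrix(rnorm(100), 10, 10)
    y <- rnorm(10)
    supp <- sort(sample(10, 3))
    expect_lt(rel_err(refit_restricted(X, y, supp), ols_oracle(X, y, supp)),
              1e-8)
  }
  # empty support: zero vector, residual is y itself
  expect_equal(refit_restricted(X, y, integer(0)), rep(0, 10))
})

test_that("restricted refit falls back to the minimum-norm solution when singular", {
  X <- cbind(c(1, 2, 3), c(2, 4, 6), c(0, 1, 0))  # first two columns collinear
  y <- c(1, 2, 3.5)
  beta <- refit_restricted(X, y, 1:3)
  # fit is still the projection
  expect_lt(max(abs(crossprod(X, y - X %*% beta))), 1e-8)
  # among solutions, minimum norm: collinear pair shares the weight 1:2
  expect_equal(beta[2] / beta[1], 2, tolerance = 1e-8)
})

test_that("BIC score has its stated closed form", {
  expect_equal(bic_score(numeric(5), 0, 10), 0)
  expect_equal(bic_score(numeric(3), 3, exp(1)), 3, tolerance = 1e-12)
  expect_equal(bic_score(c(2, 0, 0), 2, 100), 2 + 2 * log(100),
               tolerance = 1e-12)
})

test_that("threshold scan prunes a planted spurious coefficient", {
  set.seed(55)
  n <- 50; p <- 100
  X <- matrix(rnorm(n * p), n, p)
  supp <- 1:5
  beta0 <- numeric(p); beta0[supp] <- 1
  y <- drop(X %*% beta0)
  # decimation-style initial estimate: true support plus one tiny spurious entry
  beta_init <- ols_oracle(X, y, c(supp, 60))
  beta_init[60] <- 0.01
  scan <- threshold_scan(X, y, beta_init, R = 20)
  expect_false(60 %in% which(scan$beta_final != 0))
  expect_identical(which(scan$beta_final != 0), supp)
  # the pruned support must indeed score a lower BIC than the full one
  bic_full <- bic_score(y - X %*% refit_restricted(X, y, c(supp, 60)), 6, n)
  bic_pruned <- bic_score(y - X %*% refit_restricted(X, y, supp), 5, n)
  expect_lt(bic_pruned, bic_full)
  expect_equal(min(scan$bic_trace), bic_pruned, tolerance = 1e-8)
})

test_that("scan at tau = 0 reproduces the decimation support and its refit", {
  set.seed(56)
  inst <- make_instance(40, 80, 4, sigma = 0, seed = 56)
  beta_init <- ols_oracle(inst$X, inst$y, inst$support)
  scan <- threshold_scan(inst$X, inst$y, beta_init)
  expect_identical(scan$support_trace[1], length(inst$support))
  expect_identical(which(scan$beta_final != 0), inst$support)
  expect_lt(rel_err(scan$beta_final, beta_init), 1e-10)
})

test_that("retained support shrinks monotonically along the tau grid", {
  set.seed(57)
  inst <- make_instance(60, 150, 10, sigma = 1, seed = 57)
  st <- run_decimation(inst$X, inst$y, stopping_policy("assd", n = 60, sigma = 1))
  beta_init <- backtrack(st$records, 150L)
  scan <- threshold_scan(inst$X, inst$y, beta_init)
  expect_true(all(diff(scan$support_trace) <= 0))
  # chosen BIC is the minimum, and recomputes exactly from the returned beta
  expect_equal(scan$bic_trace[match(scan$chosen_tau, scan$tau_grid)],
               min(scan$bic_trace))
  bic_check <- bic_score(inst$y - inst$X %*% scan$beta_final,
                         sum(scan$beta_final != 0), 60)
  expect_equal(min(scan$bic_trace), bic_check, tolerance = 1e-10)
})

test_that("refit residual is orthogonal to the retained columns at every tau", {
  set.seed(58)
  inst <- make_instance(50, 120, 6, sigma = 0.5, seed = 58)
  st <- run_decimation(inst$X, inst$y, stopping_policy("assd", n = 50, sigma = 0.5))
  beta_init <- backtrack(st$records, 120L)
  scan <- threshold_scan(inst$X, inst$y, beta_init, R = 5, tau_step = 1)
  resid <- inst$y - inst$X %*% scan$beta_final
  keep <- which(scan$beta_final != 0)
  expect_lt(max(abs(crossprod(inst$X[, keep, drop = FALSE], resid))), 1e-6)
})

test_that("degenerate uncertainty scale collapses the scan to tau = 0", {
  set.seed(59)
  X <- matrix(rnorm(50), 10, 5)
  beta_init <- c(0.5, 0.5, 2, -3, 0)   # lower half identical -> sigma_hat = 0
  y <- drop(X %*% beta_init)
  scan <- threshold_scan(X, y, beta_init)
  expect_true(scan$degenerate)
  expect_identical(scan$tau_grid, 0)
  expect_identical(which(scan$beta_final != 0), 1:4)
})
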