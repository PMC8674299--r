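test_that("generators are deterministic given a seed", {
  expect_identical(gen_gaussian_ar(20, 10, 0.5, seed = 3),
                   gen_gaussian_ar(20, 10, 0.5, seed = 3))
  expect_identical(gen_structured(15, 12, 5, seed = 4),
                   gen_structured(15, 12, 5, seed = 4))
  expect_identical(gen_response(diag(4), rep(1, 4), 1, seed = 5),
                   gen_response(diag(4), rep(1, 4), 1, seed = 5))
  cf1 <- gen_coefficients(30, 5, "uniform_signed", seed = 6)
  cf2 <- gen_coefficients(30, 5, "uniform_signed", seed = 6)
  expect_identical(cf1, cf2)
})

test_that("AR rows have the prescribed geometric correlation profile", {
  X <- gen_gaussian_ar(5000, 10, 0.7, seed = 11)
  cors <- cor(X)
  lag1 <- mean(diag(cors[-1, -10]))
  lag2 <- mean(diag(cors[-(1:2), -(9:10)]))
  expect_lt(abs(lag1 - 0.7), 0.05)
  expect_lt(abs(lag2 - 0.49), 0.05)
  # variance stays unit along the chain
  expect_lt(max(abs(apply(X, 2, var) - 1)), 0.1)
  # pi = 0 reduces to i.i.d. N(0,1)
  X0 <- gen_gaussian_ar(5000, 10, 0, seed = 12)
  off <- cor(X0); diag(off) <- 0
  expect_lt(max(abs(off)), 0.05)
  expect_error(gen_gaussian_ar(10, 5, 1), "pi_cor")
})

test_that("structured matrices have rank bounded by the inner dimension", {
  X <- gen_structured(30, 40, 6, seed = 13)
  expect_identical(qr(X)$rank, 6L)
  # r above n: generic full row rank
  X2 <- gen_structured(20, 50, 25, seed = 14)
  expect_identical(qr(X2)$rank, 20L)
})

test_that("coefficient laws produce the stated supports and ranges", {
  cf <- gen_coefficients(200, 20, "uniform_pos", seed = 21)
  expect_length(cf$support, 20)
  expect_true(all(cf$beta0[cf$support] >= 0.5 & cf$beta0[cf$support] <= 1))
  expect_true(all(cf$beta0[-cf$support] == 0))

  cf <- gen_coefficients(200, 20, "uniform_wide", seed = 22)
  expect_true(all(cf$beta0[cf$support] >= 0.2 & cf$beta0[cf$support] <= 1))

  cf <- gen_coefficients(200, 20, "weak_sparsity", seed = 23)
  expect_true(all(cf$beta0[-cf$support] == 0.001))
  expect_true(all(cf$beta0[cf$support] >= 0.5))

  # signed law: both signs, magnitudes in [0.5, 1], balance near 50/50
  cf <- gen_coefficients(20000, 10000, "uniform_signed", seed = 24)
  vals <- cf$beta0[cf$support]
  expect_true(all(abs(vals) >= 0.5 & abs(vals) <= 1))
  expect_lt(abs(mean(vals > 0) - 0.5), 3 * 0.5 / sqrt(10000))

  cf <- gen_coefficients(50, 0, "uniform_pos", seed = 25)
  expect_identical(cf$support, integer(0))
  expect_equal(cf$beta0, numeric(50))
})

test_that("response noise has the requested variance", {
  set.seed(31)
  X <- matrix(rnorm(5000 * 3), 5000, 3)
  beta0 <- c(1, -1, 0.5)
  y0 <- gen_response(X, beta0, 0, seed = 32)
  expect_equal(y0, drop(X %*% beta0))
  y1 <- gen_response(X, beta0, 1, seed = 33)
  expect_lt(abs(var(y1 - y0) - 1), 0.1)
  expect_error(gen_response(X, c(1, 2), 1), "dimension mismatch")
})

test_that("replicates are reproducible and independent of the rep count", {
  sc <- sim_scenario(30, 60, 5, "gaussian_ar", pi_cor = 0.3, sigma2 = 0.5,
                     reps = 10, seed = 77)
  p3a <- sim_problem(sc, 3)
  sc2 <- sim_scenario(30, 60, 5, "gaussian_ar", pi_cor = 0.3, sigma2 = 0.5,
                      reps = 96, seed = 77)   # more reps, same master seed
  p3b <- sim_problem(sc2, 3)
  expect_identical(p3a$X, p3b$X)
  expect_identical(p3a$y, p3b$y)
  expect_identical(p3a$beta0, p3b$beta0)
  # different reps differ in all components
  p4 <- sim_problem(sc, 4)
  expect_false(identical(p3a$X, p4$X))
  expect_false(identical(p3a$beta0, p4$beta0))
})

test_that("scenario validation rejects inconsistent designs", {
  expect_error(sim_scenario(100, 50, 5), "s0 < n < p")
  expect_error(sim_scenario(50, 100, 60), "s0 < n < p")
  expect_error(sim_scenario(50, 100, 5, sigma2 = -1), "sigma2")
  expect_error(sim_scenario(50, 100, 5, "structured"), "inner rank")
  expect_error(sim_scenario(50, 100, 5, "user_matrix"), "need the matrix")
})

test_that("scenarios round-trip through the flat key-value format", {
  sc <- sim_scenario(40, 90, 6, "structured", r = 15, coef_law = "uniform_wide",
                     sigma2 = 0.5, reps = 12, seed = 9)
  path <- tempfile(fileext = ".cfg")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc[names(sc) != "X"], sc2[names(sc2) != "X"])
})

test_that("matrix subsampling is seeded and respects bounds", {
  X <- matrix(seq_len(100), 10, 10)
  S1 <- subsample_matrix(X, 4, 6, seed = 2)
  S2 <- subsample_matrix(X, 4, 6, seed = 2)
  expect_identical(S1, S2)
  expect_identical(dim(S1), c(4L, 6L))
  expect_true(all(S1 %in% X))
  expect_error(subsample_matrix(X, 11, 5, seed = 1), "beyond")
})
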