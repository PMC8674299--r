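#' Simulation scenario for the replicated study designs
#'
#' Describes one generative setting of the simulation study: the measurement
#' matrix family, its dimensions and correlation parameter, the sparse
#' coefficient law, the noise variance, the number of replicates and the
#' master seed.  Replicates are fully reproducible: the master seed is
#' expanded into independent child seeds per replicate and per component
#' (matrix / coefficients / noise), so replicate k is unchanged when
#' \code{reps} is raised.
#'
#' @param n sample count.
#' @param p predictor count (p > n is the regime of interest).
#' @param s0 number of truly nonzero coefficients (s0 < n).
#' @param matrix_family \code{"gaussian_ar"} (rows i.i.d. N(0, Sigma) with
#'   \eqn{\Sigma_{ij} = \pi^{|i-j|}}), \code{"structured"} (X = X1 X2 of
#'   inner rank r, factor entries i.i.d. N(0,1)), or \code{"user_matrix"}
#'   (a fixed matrix supplied in \code{X}, e.g. loaded from file).
#' @param pi_cor AR(1) correlation in [0, 1) for \code{"gaussian_ar"}.
#' @param r inner rank for \code{"structured"}.
#' @param coef_law one of \code{"uniform_pos"} (U[0.5, 1]),
#'   \code{"uniform_signed"} (U[-1, -0.5] or U[0.5, 1] with equal
#'   probability), \code{"uniform_wide"} (U[0.2, 1]),
#'   \code{"weak_sparsity"} (s0 entries U[0.5, 1], all others 0.001).
#' @param sigma2 noise variance (>= 0).
#' @param reps number of replicates.
#' @param seed master seed (integer).
#' @param X fixed design matrix, required for \code{"user_matrix"}.
#' @return a list of class \code{"assd_scenario"}.
#' @export
sim_scenario <- function(n, p, s0,
                         matrix_family = c("gaussian_ar", "structured",
                                           "user_matrix"),
                         pi_cor = 0, r = NULL,
                         coef_law = c("uniform_pos", "uniform_signed",
                                      "uniform_wide", "weak_sparsity"),
                         sigma2 = 1, reps = 96, seed = 1, X = NULL) {
  matrix_family <- match.arg(matrix_family)
  coef_law <- match.arg(coef_law)
  if (!(s0 < n && n < p))
    stop("scenario requires s0 < n < p")
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  if (pi_cor < 0 || pi_cor >= 1) stop("pi_cor must lie in [0, 1)")
  if (matrix_family == "structured" && (is.null(r) || r < 1))
    stop("structured matrices need an inner rank r >= 1")
  if (matrix_family == "user_matrix") {
    if (is.null(X)) stop("user_matrix scenarios need the matrix X")
    X <- as.matrix(X)
    if (nrow(X) != n || ncol(X) != p)
      stop("supplied X does not match n and p")
  }
  structure(list(n = as.integer(n), p = as.integer(p), s0 = as.integer(s0),
                 matrix_family = matrix_family, pi_cor = pi_cor,
                 r = if (is.null(r)) NA_integer_ else as.integer(r),
                 coef_law = coef_law, sigma2 = sigma2,
                 reps = as.integer(reps), seed = as.integer(seed),
                 X = X),
            class = "assd_scenario")
}

#' @export
print.assd_scenario <- function(x, ...) {
  fam <- switch(x$matrix_family,
                gaussian_ar = sprintf("Gaussian AR rows (pi = %g)", x$pi_cor),
                structured = sprintf("structured X1 X2 (inner rank r = %d)", x$r),
                user_matrix = "user-supplied matrix")
  cat(sprintf("Simulation scenario: n = %d, p = %d, s0 = %d\n", x$n, x$p, x$s0))
  cat(sprintf("  design: %s\n  coefficients: %s, noise variance %g\n",
              fam, x$coef_law, x$sigma2))
  cat(sprintf("  %d replicates, master seed %d\n", x$reps, x$seed))
  invisible(x)
}

# deterministic child seed: master seed -> replicate -> component.
# component ids: 1 = matrix, 2 = coefficients, 3 = noise.  Kept below 2^31.
child_seed <- function(master, rep, component) {
  base <- (abs(as.integer(master)) %% 1000003L)
  as.integer((base * 2011L + as.integer(rep) * 131L +
                as.integer(component)) %% .Machine$integer.max)
}

#' Correlated Gaussian design matrix
#'
#' Rows drawn i.i.d. from N(0, Sigma) with \eqn{\Sigma_{ij} = \pi^{|i-j|}},
#' realized by the AR(1) recursion across columns: the first column is
#' standard normal and column j is \eqn{\pi} times column j-1 plus
#' \eqn{\sqrt{1-\pi^2}} fresh noise.  \code{pi_cor = 0} gives i.i.d. N(0, 1)
#' entries.
#'
#' @param n,p matrix dimensions.
#' @param pi_cor AR(1) correlation in [0, 1).
#' @param seed integer seed (the generator is deterministic given it).
#' @return an n-by-p numeric matrix.
#' @export
gen_gaussian_ar <- function(n, p, pi_cor = 0, seed = 1) {
  if (pi_cor < 0 || pi_cor >= 1) stop("pi_cor must lie in [0, 1)")
  set.seed(seed)
  E <- matrix(stats::rnorm(n * p), n, p)
  if (pi_cor == 0) return(E)
  X <- E
  sc <- sqrt(1 - pi_cor^2)
  for (j in 2:p) X[, j] <- pi_cor * X[, j - 1L] + sc * E[, j]
  X
}

#' Low-rank structured design matrix
#'
#' X = X1 X2 with X1 (n-by-r) and X2 (r-by-p) filled with i.i.d. N(0, 1)
#' entries.  The inner rank r controls the correlation among the columns of
#' X: r far above n gives nearly uncorrelated entries, while r close to n
#' gives a strongly correlated, rank-limited design.
#'
#' @param n,p outer dimensions.
#' @param r inner rank (>= 1).
#' @param seed integer seed.
#' @return an n-by-p numeric matrix of rank at most min(n, r, p).
#' @export
gen_structured <- function(n, p, r, seed = 1) {
  if (r < 1) stop("inner rank r must be at least 1")
  set.seed(seed)
  X1 <- matrix(stats::rnorm(n * r), n, r)
  X2 <- matrix(stats::rnorm(r * p), r, p)
  X1 %*% X2
}

#' Sparse true coefficient vector
#'
#' Draws a uniform random s0-subset of 1..p as the support and fills it
#' according to \code{coef_law}; off-support entries are 0 (or 0.001 under
#' \code{"weak_sparsity"}, which emulates many tiny but nonzero effects).
#'
#' @param p length of the vector.
#' @param s0 support size (s0 <= p).
#' @param coef_law see [sim_scenario()].
#' @param seed integer seed.
#' @return list with \code{beta0} (length p) and \code{support}
#'   (sorted integer vector of length s0).
#' @export
gen_coefficients <- function(p, s0,
                             coef_law = c("uniform_pos", "uniform_signed",
                                          "uniform_wide", "weak_sparsity"),
                             seed = 1) {
  coef_law <- match.arg(coef_law)
  if (s0 > p) stop("s0 cannot exceed p")
  set.seed(seed)
  beta0 <- if (coef_law == "weak_sparsity") rep(0.001, p) else numeric(p)
  support <- integer(0)
  if (s0 > 0) {
    support <- sort(sample.int(p, s0))
    vals <- switch(coef_law,
                   uniform_pos = ,
                   weak_sparsity = stats::runif(s0, 0.5, 1),
                   uniform_signed = stats::runif(s0, 0.5, 1) *
                     sample(c(-1, 1), s0, replace = TRUE),
                   uniform_wide = stats::runif(s0, 0.2, 1))
    beta0[support] <- vals
  }
  list(beta0 = beta0, support = support)
}

#' Noisy response vector
#'
#' y = X beta0 + eps with eps i.i.d. N(0, sigma2); sigma2 = 0 returns the
#' exact linear response.
#'
#' @param X design matrix.
#' @param beta0 coefficient vector (length ncol(X)).
#' @param sigma2 noise variance (>= 0).
#' @param seed integer seed.
#' @return numeric vector of length nrow(X).
#' @export
gen_response <- function(X, beta0, sigma2 = 1, seed = 1) {
  X <- as.matrix(X)
  if (length(beta0) != ncol(X))
    stop(sprintf("dimension mismatch: X has %d columns but beta0 has length %d",
                 ncol(X), length(beta0)))
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  mu <- as.numeric(X %*% beta0)
  if (sigma2 == 0) return(mu)
  set.seed(seed)
  mu + stats::rnorm(nrow(X), 0, sqrt(sigma2))
}

#' Realize one replicate of a scenario
#'
#' Generates (X, beta0, y) for replicate \code{rep} of a scenario, using
#' independent child seeds for the matrix, the coefficients and the noise.
#' For \code{"user_matrix"} scenarios the fixed matrix is reused across
#' replicates and only coefficients and noise are redrawn.
#'
#' @param scenario an \code{"assd_scenario"}.
#' @param rep replicate index (1-based).
#' @return list with \code{X}, \code{y}, \code{beta0}, \code{support},
#'   \code{sigma} (noise s.d.), \code{rep}.
#' @export
sim_problem <- function(scenario, rep = 1L) {
  stopifnot(inherits(scenario, "assd_scenario"))
  X <- switch(scenario$matrix_family,
              gaussian_ar = gen_gaussian_ar(scenario$n, scenario$p,
                                            scenario$pi_cor,
                                            child_seed(scenario$seed, rep, 1L)),
              structured = gen_structured(scenario$n, scenario$p, scenario$r,
                                          child_seed(scenario$seed, rep, 1L)),
              user_matrix = scenario$X)
  cf <- gen_coefficients(scenario$p, scenario$s0, scenario$coef_law,
                         child_seed(scenario$seed, rep, 2L))
  y <- gen_response(X, cf$beta0, scenario$sigma2,
                    child_seed(scenario$seed, rep, 3L))
  list(X = X, y = y, beta0 = cf$beta0, support = cf$support,
       sigma = sqrt(scenario$sigma2), rep = as.integer(rep))
}

#' Randomly subsample a user-supplied design matrix
#'
#' Utility for large real-world matrices (e.g. a gene-expression matrix):
#' draws uniform random subsets of rows and columns.
#'
#' @param X matrix to subsample.
#' @param n,p target numbers of rows and columns.
#' @param seed integer seed.
#' @return an n-by-p submatrix (rows and columns in sampled order).
#' @export
subsample_matrix <- function(X, n, p, seed = 1) {
  X <- as.matrix(X)
  if (n > nrow(X) || p > ncol(X))
    stop("cannot subsample beyond the matrix dimensions")
  set.seed(seed)
  X[sample.int(nrow(X), n), sample.int(ncol(X), p), drop = FALSE]
}

#' Write a simulated problem as delimited text
#'
#' Writes X, y and beta0 as three CSV files (\code{X.csv}, \code{y.csv},
#' \code{beta0.csv}) under \code{dir}, readable back with [load_problem()].
#'
#' @param problem list with X, y and optionally beta0 (as from
#'   [sim_problem()]).
#' @param dir output directory (created if needed).
#' @param sep field separator (default comma).
#' @return invisibly, the paths written.
#' @export
write_problem <- function(problem, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(X = file.path(dir, "X.csv"), y = file.path(dir, "y.csv"))
  utils::write.table(problem$X, paths[["X"]], sep = sep,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(problem$y, paths[["y"]], sep = sep,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(problem$beta0)) {
    paths[["beta0"]] <- file.path(dir, "beta0.csv")
    utils::write.table(problem$beta0, paths[["beta0"]], sep = sep,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Serialize / read a scenario as a flat key-value file
#'
#' @param scenario an \code{"assd_scenario"} (without a user matrix).
#' @param path file path.
#' @return \code{write_scenario} returns the path invisibly;
#'   \code{read_scenario} returns the reconstructed scenario.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "assd_scenario"))
  if (scenario$matrix_family == "user_matrix")
    stop("user_matrix scenarios cannot be serialized (matrix not embedded)")
  kv <- scenario[c("n", "p", "s0", "matrix_family", "pi_cor", "r",
                   "coef_law", "sigma2", "reps", "seed")]
  writeLines(paste(names(kv), vapply(kv, as.character, character(1)),
                   sep = " = "), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  r <- suppressWarnings(as.integer(vals[["r"]]))
  sim_scenario(n = as.integer(vals[["n"]]), p = as.integer(vals[["p"]]),
               s0 = as.integer(vals[["s0"]]),
               matrix_family = vals[["matrix_family"]],
               pi_cor = as.numeric(vals[["pi_cor"]]),
               r = if (is.na(r)) NULL else r,
               coef_law = vals[["coef_law"]],
               sigma2 = as.numeric(vals[["sigma2"]]),
               reps = as.integer(vals[["reps"]]),
               seed = as.integer(vals[["seed"]]))
}
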