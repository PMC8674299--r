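#' Variable-selection and estimation metrics
#'
#' Compares an estimated coefficient vector against the truth: TP (true
#' support indices estimated nonzero), FP (estimated-nonzero indices outside
#' the true support), RE (relative l2 error
#' \eqn{\|\beta - \beta^0\|_2 / \|\beta^0\|_2}) and the exact-recovery flag
#' (estimated support identical to the true support).  "Nonzero" means
#' strictly different from zero.
#'
#' @param beta estimated coefficient vector.
#' @param beta0 true coefficient vector (not identically zero).
#' @return list with \code{tp}, \code{fp}, \code{re}, \code{exact}.
#' @export
compute_metrics <- function(beta, beta0) {
  if (length(beta) != length(beta0))
    stop("beta and beta0 must have equal length")
  if (all(beta0 == 0))
    stop("relative error undefined: beta0 is identically zero")
  s_est <- beta != 0
  s_true <- beta0 != 0
  tp <- sum(s_est & s_true)
  fp <- sum(s_est & !s_true)
  re <- sqrt(sum((beta - beta0)^2)) / sqrt(sum(beta0^2))
  list(tp = as.integer(tp), fp = as.integer(fp), re = re,
       exact = identical(which(s_est), which(s_true)))
}

#' Replicated simulation experiment
#'
#' Runs the configured solver on every replicate of a scenario and
#' aggregates the metrics (mean and s.d. of TP, FP, RE and elapsed time, and
#' the fraction of replicates with exact support recovery).  A replicate on
#' which the solver errors is recorded as failed with its message and
#' excluded from the aggregates.
#'
#' @param scenario an \code{"assd_scenario"} from [sim_scenario()].
#' @param method solver variant: \code{"assd"}, \code{"ssd1"} or
#'   \code{"ssd_naive"}.
#' @param reps number of replicates; defaults to \code{scenario$reps}.
#' @param sigma noise s.d. passed to the solver; defaults to
#'   \code{sqrt(scenario$sigma2)} (the study treats the noise level as
#'   known).  Pass \code{NA} to fit with sigma unknown.
#' @param ... further arguments to [assd()] (e.g. \code{L_max}, \code{R},
#'   \code{eta}).
#' @return an object of class \code{"assd_experiment"}: list with
#'   \code{scenario}, \code{method}, \code{per_rep} (data frame with one row
#'   per replicate: rep, tp, fp, re, exact, L, elapsed, failed, reason) and
#'   \code{summary} (data frame of metric, mean, sd), plus
#'   \code{exact_recovery_prob} and \code{n_failed}.
#' @export
run_experiment <- function(scenario, method = c("assd", "ssd1", "ssd_naive"),
                           reps = NULL, sigma = NULL, ...) {
  stopifnot(inherits(scenario, "assd_scenario"))
  method <- match.arg(method)
  if (is.null(reps)) reps <- scenario$reps
  if (is.null(sigma)) sigma <- sqrt(scenario$sigma2)
  if (length(sigma) == 1L && is.na(sigma)) sigma <- NULL

  rows <- vector("list", reps)
  for (k in seq_len(reps)) {
    prob <- sim_problem(scenario, k)
    t0 <- proc.time()[["elapsed"]]
    fit <- tryCatch(assd(prob$X, prob$y, method = method, sigma = sigma, ...),
                    error = function(e) e)
    el <- proc.time()[["elapsed"]] - t0
    if (inherits(fit, "error")) {
      rows[[k]] <- data.frame(rep = k, tp = NA_integer_, fp = NA_integer_,
                              re = NA_real_, exact = NA, L = NA_integer_,
                              elapsed = el, failed = TRUE,
                              reason = conditionMessage(fit))
    } else {
      met <- compute_metrics(coef(fit), prob$beta0)
      rows[[k]] <- data.frame(rep = k, tp = met$tp, fp = met$fp, re = met$re,
                              exact = met$exact, L = fit$L, elapsed = el,
                              failed = FALSE, reason = "")
    }
  }
  per_rep <- do.call(rbind, rows)
  ok <- !per_rep$failed
  agg <- function(v) c(mean = mean(v[ok]), sd = stats::sd(v[ok]))
  summ <- data.frame(metric = c("tp", "fp", "re", "elapsed"),
                     rbind(agg(per_rep$tp), agg(per_rep$fp),
                           agg(per_rep$re), agg(per_rep$elapsed)))
  structure(list(scenario = scenario, method = method, per_rep = per_rep,
                 summary = summ,
                 exact_recovery_prob = mean(per_rep$exact[ok]),
                 n_failed = sum(!ok)),
            class = "assd_experiment")
}

#' @export
print.assd_experiment <- function(x, ...) {
  s <- x$summary
  fmt <- function(metric, digits = 4) {
    i <- match(metric, s$metric)
    sprintf("%s (%s)", signif(s$mean[i], digits), signif(s$sd[i], 3))
  }
  cat(sprintf("Experiment: %s on %d replicates (%d failed)\n",
              toupper(x$method), nrow(x$per_rep), x$n_failed))
  print(x$scenario)
  cat(sprintf("  TP %s   FP %s   RE %s   time %s s\n",
              fmt("tp"), fmt("fp"), fmt("re"), fmt("elapsed")))
  cat(sprintf("  exact support recovery in %.0f%% of replicates\n",
              100 * x$exact_recovery_prob))
  invisible(x)
}

#' Parameter sweep over a scenario dimension
#'
#' Repeats [run_experiment()] along a grid over one of n, p or s0, holding
#' the rest of the base scenario fixed, and returns the per-grid-point
#' summaries plus a long-format table of metric curves suitable for writing
#' as CSV (the RE/TP/FP/exact-recovery curves of the parameter-influence
#' study).
#'
#' @param param one of \code{"n"}, \code{"p"}, \code{"s0"}.
#' @param values grid values for the swept parameter.
#' @param base an \code{"assd_scenario"} supplying all other settings.
#' @param method solver variant.
#' @param reps replicates per grid point (defaults to \code{base$reps}).
#' @param ... further solver arguments (e.g. \code{L_max = 0.5 * n} style
#'   overrides can be expressed via \code{L_max_fraction}).
#' @param L_max_fraction if given, sets \code{L_max = floor(fraction * n)}
#'   at each grid point (used for sparsity sweeps up to large s0).
#' @return list of class \code{"assd_sweep"} with \code{param},
#'   \code{values}, \code{experiments} (list of \code{"assd_experiment"}) and
#'   \code{curves} (data frame: value, metric, mean, sd).
#' @export
sweep_experiment <- function(param = c("n", "p", "s0"), values, base,
                             method = "assd", reps = NULL,
                             L_max_fraction = NULL, ...) {
  param <- match.arg(param)
  stopifnot(inherits(base, "assd_scenario"))
  experiments <- vector("list", length(values))
  curve_rows <- list()
  for (i in seq_along(values)) {
    args <- base[c("n", "p", "s0", "matrix_family", "pi_cor", "coef_law",
                   "sigma2", "reps", "seed")]
    args$r <- if (is.na(base$r)) NULL else base$r
    args[[param]] <- values[i]
    sc <- do.call(sim_scenario, args)
    extra <- list(...)
    if (!is.null(L_max_fraction))
      extra$L_max <- max(1L, floor(L_max_fraction * sc$n))
    ex <- do.call(run_experiment,
                  c(list(scenario = sc, method = method, reps = reps), extra))
    experiments[[i]] <- ex
    s <- ex$summary
    curve_rows[[i]] <- rbind(
      data.frame(value = values[i], metric = s$metric, mean = s$mean,
                 sd = s$sd),
      data.frame(value = values[i], metric = "exact_recovery_prob",
                 mean = ex$exact_recovery_prob, sd = NA_real_))
  }
  structure(list(param = param, values = values, experiments = experiments,
                 curves = do.call(rbind, curve_rows)),
            class = "assd_sweep")
}

#' @export
print.assd_sweep <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d points)\n", x$param, length(x$values)))
  wide <- stats::reshape(x$curves[x$curves$metric != "elapsed",
                                  c("value", "metric", "mean")],
                         idvar = "value", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Write experiment tables as CSV
#'
#' Writes the per-replicate long table and the summary table of an
#' experiment (or the curves of a sweep) to CSV files under \code{dir}.
#'
#' @param x an \code{"assd_experiment"} or \code{"assd_sweep"}.
#' @param dir output directory.
#' @param prefix file-name prefix (default \code{"experiment"}).
#' @return invisibly, the paths written.
#' @export
write_results <- function(x, dir, prefix = "experiment") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (inherits(x, "assd_experiment")) {
    p1 <- file.path(dir, paste0(prefix, "_per_rep.csv"))
    p2 <- file.path(dir, paste0(prefix, "_summary.csv"))
    utils::write.csv(x$per_rep, p1, row.names = FALSE)
    utils::write.csv(x$summary, p2, row.names = FALSE)
    paths <- c(p1, p2)
  } else if (inherits(x, "assd_sweep")) {
    p1 <- file.path(dir, paste0(prefix, "_curves.csv"))
    utils::write.csv(x$curves, p1, row.names = FALSE)
    paths <- p1
  } else stop("x must be an assd_experiment or assd_sweep")
  invisible(paths)
}
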