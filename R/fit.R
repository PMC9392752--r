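#' Mean squared error between two group profiles
#'
#' The fitting objective: the mean over the four behavioural indices of the
#' squared difference of group means,
#' `MSE = (1/4) * sum_k (mean_model[k] - mean_target[k])^2`.
#' Dispersion (the SDs) does not enter the objective.
#'
#' @param model,target [wcst_group_profile()] objects (or [wcst_simulate_group()]
#'   results).
#' @return A single non-negative number.
#' @examples
#' a <- wcst_group_profile(c(cc = 5, pe = 10, npe = 10, fms = 1))
#' b <- wcst_group_profile(c(cc = 5, pe = 12, npe = 10, fms = 1))
#' wcst_mse(a, b)  # 1
#' @export
wcst_mse <- function(model, target) {
  model <- as_group_profile(model)
  target <- as_group_profile(target)
  mean((model$mean - target$mean)^2)
}

#' Fit agent parameters to a group profile by random search
#'
#' The group-level fitting procedure: sample `n_configs` parameter vectors
#' uniformly within `bounds`, simulate a group of `n_runs` sessions for each,
#' and rank the configurations by the mean squared error ([wcst_mse()])
#' between the simulated and target index means.  Ties keep sampling order.
#' The whole search is a deterministic function of
#' `(target, n_configs, n_runs, bounds, seed)`.
#'
#' @param target The target [wcst_group_profile()] (e.g. a published group
#'   summary or a [wcst_synthetic_target()]).
#' @param n_configs Number of random configurations (default 2000).
#' @param n_runs Sessions simulated per configuration; defaults to the
#'   target's sample size.
#' @param bounds Named list of `c(lower, upper)` sampling intervals for
#'   `mu`, `phi`, `tau`, `lam`; defaults to the full legal ranges
#'   (`tau` lower-bounded at 0.01).
#' @param seed Master seed for the search.
#' @return An object of class `"wcst_fit"`: a list with `configs` (data frame
#'   of every evaluated configuration with its `mse`, in sampling order),
#'   `ranking` (row indices sorted by ascending `mse`), `best`
#'   (the best-fitting [wcst_params()]), `target`, `n_runs` and `seed`.
#'   Supports `print`, `summary`, `coef`, `predict`, `simulate` and `plot`.
#' @examples
#' target <- wcst_synthetic_target(wcst_params(0.2, 0.2, 0.1, 0.3),
#'                                 n = 10, seed = 1)
#' fit <- wcst_fit(target, n_configs = 25, n_runs = 5, seed = 1)
#' coef(fit)
#' @export
wcst_fit <- function(target, n_configs = 2000L, n_runs = NULL, bounds = NULL,
                     seed = NULL) {
  target <- as_group_profile(target)
  n_configs <- as.integer(n_configs)
  stopifnot(n_configs >= 1L)
  if (is.null(n_runs)) n_runs <- target$n
  n_runs <- as.integer(n_runs)
  stopifnot(n_runs >= 1L)
  bounds <- resolve_bounds(bounds)

  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(b) runif(n_configs, b[1], b[2])
  configs <- data.frame(mu = draw(bounds$mu), phi = draw(bounds$phi),
                        tau = draw(bounds$tau), lam = draw(bounds$lam))
  group_seeds <- sample.int(.Machine$integer.max, n_configs)

  configs$mse <- vapply(seq_len(n_configs), function(i) {
    g <- wcst_simulate_group(wcst_params(configs$mu[i], configs$phi[i],
                                         configs$tau[i], configs$lam[i]),
                             n = n_runs, seed = group_seeds[i])
    wcst_mse(g, target)
  }, numeric(1))

  ranking <- order(configs$mse)  # stable: ties keep sampling order
  best <- configs[ranking[1L], ]
  structure(list(
    configs = configs, ranking = ranking,
    best = wcst_params(best$mu, best$phi, best$tau, best$lam),
    mse = best$mse, target = target, n_runs = n_runs, bounds = bounds,
    seed = seed), class = "wcst_fit")
}

resolve_bounds <- function(bounds) {
  default <- list(mu = c(0, 1), phi = c(0, 1), tau = c(0.01, 1), lam = c(0, 1))
  if (is.null(bounds)) return(default)
  for (nm in names(bounds)) {
    if (!nm %in% names(default)) stop("unknown parameter in bounds: ", nm)
    b <- as.numeric(bounds[[nm]])
    if (length(b) != 2L || anyNA(b) || b[1] > b[2] ||
        b[1] < default[[nm]][1] - 1e-12 || b[2] > 1)
      stop(sprintf("bounds for '%s' must be an interval within [%g, 1]",
                   nm, default[[nm]][1]))
    default[[nm]] <- b
  }
  default
}

#' @export
print.wcst_fit <- function(x, ...) {
  cat(sprintf("WCST random-search fit: %d configurations x %d sessions\n",
              nrow(x$configs), x$n_runs))
  cat(sprintf("best MSE: %.4g\n", x$mse))
  print(x$best)
  invisible(x)
}

#' @export
summary.wcst_fit <- function(object, top = 5L, ...) {
  top <- utils::head(object$configs[object$ranking, ], top)
  cat(sprintf("WCST random-search fit (%d configurations, %d sessions each)\n",
              nrow(object$configs), object$n_runs))
  cat("\nTarget means:\n")
  print(round(object$target$mean, 3))
  cat(sprintf("\nTop %d configurations by MSE:\n", nrow(top)))
  print(round(top, 4))
  invisible(object)
}

#' @export
coef.wcst_fit <- function(object, ...) object$best

#' Simulate from, or predict with, a fitted configuration
#'
#' `predict()` simulates a group at the best-fitting parameters and returns
#' its [wcst_group_profile()]; `simulate()` returns the per-session index
#' matrix instead.
#'
#' @param object A [wcst_fit()] object.
#' @param n,nsim Number of sessions (default: the fit's `n_runs`).
#' @param seed Seed for the simulation.
#' @param ... Unused.
#' @return A group profile (`predict`) or an `nsim` x 4 matrix (`simulate`).
#' @export
predict.wcst_fit <- function(object, n = object$n_runs, seed = NULL, ...) {
  summary(wcst_simulate_group(object$best, n = n, seed = seed))
}

#' @rdname predict.wcst_fit
#' @export
simulate.wcst_fit <- function(object, nsim = object$n_runs, seed = NULL, ...) {
  wcst_simulate_group(object$best, n = nsim, seed = seed)$profiles
}

#' @export
plot.wcst_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (nm in c("mu", "phi", "tau", "lam")) {
    plot(x$configs[[nm]], x$configs$mse, pch = 16, cex = 0.4,
         col = "grey50", log = "y", xlab = nm, ylab = "MSE", ...)
    abline(v = x$best[[nm]], col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Synthetic fitting target with known generator
#'
#' Simulates a group and returns its profile as a fitting target, recording
#' the generating parameters in the `"generator"` attribute so that
#' parameter-recovery error is measurable.
#'
#' @param params Generating [wcst_params()].
#' @param n Sessions in the synthetic group.
#' @param seed Seed for the group simulation.
#' @return A [wcst_group_profile()] with attribute `generator`.
#' @examples
#' tgt <- wcst_synthetic_target(wcst_params(0.1, 0.9, 0.2, 0.4), n = 20, seed = 1)
#' attr(tgt, "generator")
#' @export
wcst_synthetic_target <- function(params, n, seed = NULL) {
  params <- as_wcst_params(params)
  out <- summary(wcst_simulate_group(params, n = n, seed = seed))
  attr(out, "generator") <- params
  out
}
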