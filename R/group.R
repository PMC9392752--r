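#' Group behavioural profile
#'
#' Per-index mean and standard deviation of the four behavioural indices for
#' a group of sessions (simulated or taken from a published summary table),
#' together with the sample size.  This is both the summary returned by
#' [wcst_simulate_group()] and the fitting target consumed by [wcst_fit()].
#'
#' @param mean Named numeric vector of index means (`cc`, `pe`, `npe`, `fms`).
#' @param sd Named numeric vector of index standard deviations (same names);
#'   defaults to zero.
#' @param n Sample size the summary is based on.
#' @return An object of class `"wcst_group_profile"`.
#' @examples
#' wcst_group_profile(c(cc = 6, pe = 10.08, npe = 8.62, fms = 0.38),
#'                    c(cc = 0, pe = 2.3, npe = 3.36, fms = 0.62), n = 13)
#' @export
wcst_group_profile <- function(mean, sd = NULL, n = 1L) {
  idx <- c("cc", "pe", "npe", "fms")
  mean <- unlist(mean)[idx]
  if (anyNA(mean) || any(mean < 0))
    stop("mean must supply non-negative cc, pe, npe and fms")
  if (is.null(sd)) sd <- stats::setNames(numeric(4), idx)
  sd <- unlist(sd)[idx]
  if (anyNA(sd) || any(sd < 0)) stop("sd must be non-negative for every index")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive count")
  structure(list(mean = stats::setNames(as.numeric(mean), idx),
                 sd = stats::setNames(as.numeric(sd), idx), n = n),
            class = "wcst_group_profile")
}

#' @export
print.wcst_group_profile <- function(x, digits = 2, ...) {
  cat(sprintf("WCST group profile (n = %d)\n", x$n))
  for (k in names(x$mean))
    cat(sprintf("  %-4s %6s (%s)\n", toupper(k),
                format(round(x$mean[[k]], digits), nsmall = digits),
                format(round(x$sd[[k]], digits), nsmall = digits)))
  invisible(x)
}

#' Simulate a group of sessions
#'
#' Runs `n` independent sessions of the same agent.  Per-session seeds are
#' drawn from the master seed, so the group is a deterministic function of
#' `(params, n, seed)`.
#'
#' @param params A [wcst_params()] object.
#' @param n Number of sessions.
#' @param seed Master seed.
#' @param engine Simulation engine, see [wcst_session()].
#' @return An object of class `"wcst_group"`: a list with `profiles` (n x 4
#'   matrix of per-session indices), `mean`, `sd` (population SD, divisor
#'   `n`), `params`, `n` and `seed`.  `summary()` converts it to a
#'   [wcst_group_profile()].
#' @examples
#' g <- wcst_simulate_group(wcst_params(0.17, 0.09, 0.12, 0.23), n = 13, seed = 1)
#' summary(g)
#' @export
wcst_simulate_group <- function(params, n, seed = NULL, engine = "cpp") {
  params <- as_wcst_params(params)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  session_seeds <- sample.int(.Machine$integer.max, n)
  profiles <- matrix(0L, n, 4, dimnames = list(NULL, c("cc", "pe", "npe", "fms")))
  if (engine == "cpp") {
    # fast path: only the index counts are needed per session
    for (i in seq_len(n)) {
      set.seed(session_seeds[i])
      profiles[i, ] <- .cpp_session(params[["mu"]], params[["phi"]],
                                    params[["tau"]], params[["lam"]])$counts
    }
  } else {
    for (i in seq_len(n))
      profiles[i, ] <- wcst_session(params, seed = session_seeds[i],
                                    engine = engine)$profile
  }
  m <- colMeans(profiles)
  s <- sqrt(colMeans(profiles^2) - m^2)  # population SD
  structure(list(profiles = profiles, mean = m, sd = s, params = params,
                 n = n, seed = seed), class = "wcst_group")
}

#' @export
print.wcst_group <- function(x, digits = 2, ...) {
  cat(sprintf("WCST simulated group: %d sessions%s\n", x$n,
              if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")") else ""))
  print(x$params)
  print(summary(x), digits = digits)
  invisible(x)
}

#' @export
summary.wcst_group <- function(object, ...) {
  wcst_group_profile(object$mean, object$sd, object$n)
}

as_group_profile <- function(x) {
  if (inherits(x, "wcst_group_profile")) return(x)
  if (inherits(x, "wcst_group")) return(summary(x))
  stop("expected a wcst_group_profile or wcst_group object")
}

# per-session index matrix from whatever group representation is passed
profile_matrix <- function(x) {
  if (inherits(x, "wcst_group")) return(x$profiles)
  x <- as.matrix(as.data.frame(x))
  if (!all(c("cc", "pe", "npe", "fms") %in% colnames(x)))
    stop("per-session profiles need columns cc, pe, npe, fms")
  x[, c("cc", "pe", "npe", "fms"), drop = FALSE]
}
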