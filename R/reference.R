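# Best-fit parameter sets and the behavioural profiles of the corresponding
# model samples for the eight reference groups (control / autism-spectrum
# condition x children / teenagers / young adults / middle adults), together
# with the human sample sizes the groups were fitted at.  A second,
# independently transcribed copy ships in inst/extdata/reference_groups.json;
# the test suite cross-checks the two to guard against transcription drift.
.wcst_reference <- list(
  control_children = list(
    condition = "control", age = "children", n = 52L, n_alt = 42L,
    params = c(mu = 0.08, phi = 0.37, tau = 0.18, lam = 0.17),
    mean = c(cc = 5.06, pe = 12.27, npe = 14.13, fms = 3.06),
    sd   = c(cc = 0.93, pe = 3.26,  npe = 4.44,  fms = 1.75)),
  control_teenagers = list(
    condition = "control", age = "teenagers", n = 13L, n_alt = NA_integer_,
    params = c(mu = 0.17, phi = 0.09, tau = 0.12, lam = 0.23),
    mean = c(cc = 6.0,  pe = 10.08, npe = 8.62,  fms = 0.38),
    sd   = c(cc = 0.0,  pe = 2.3,   npe = 3.36,  fms = 0.62)),
  control_young_adults = list(
    condition = "control", age = "young_adults", n = 10L, n_alt = NA_integer_,
    params = c(mu = 0.21, phi = 0.73, tau = 0.12, lam = 0.33),
    mean = c(cc = 5.9,  pe = 6.2,   npe = 8.5,   fms = 1.8),
    sd   = c(cc = 0.3,  pe = 1.89,  npe = 4.13,  fms = 1.72)),
  control_middle_adults = list(
    condition = "control", age = "middle_adults", n = 20L, n_alt = NA_integer_,
    params = c(mu = 0.05, phi = 0.41, tau = 0.18, lam = 0.52),
    mean = c(cc = 5.5,  pe = 7.9,   npe = 12.05, fms = 2.7),
    sd   = c(cc = 0.81, pe = 2.32,  npe = 3.53,  fms = 1.71)),
  asc_children = list(
    condition = "asc", age = "children", n = 26L, n_alt = NA_integer_,
    params = c(mu = 0.11, phi = 0.93, tau = 0.83, lam = 0.01),
    mean = c(cc = 0.12, pe = 24.77, npe = 38.04, fms = 0.69),
    sd   = c(cc = 0.32, pe = 4.48,  npe = 4.4,   fms = 1.1)),
  asc_teenagers = list(
    condition = "asc", age = "teenagers", n = 13L, n_alt = NA_integer_,
    params = c(mu = 0.20, phi = 0.19, tau = 0.14, lam = 0.0),
    mean = c(cc = 5.08, pe = 12.77, npe = 13.92, fms = 2.85),
    sd   = c(cc = 1.21, pe = 3.12,  npe = 3.12,  fms = 1.23)),
  asc_young_adults = list(
    condition = "asc", age = "young_adults", n = 9L, n_alt = NA_integer_,
    params = c(mu = 0.08, phi = 0.11, tau = 0.08, lam = 0.02),
    mean = c(cc = 5.44, pe = 32.44, npe = 14.33, fms = 0.11),
    sd   = c(cc = 0.68, pe = 10.23, npe = 5.79,  fms = 0.31)),
  asc_middle_adults = list(
    condition = "asc", age = "middle_adults", n = 27L, n_alt = NA_integer_,
    params = c(mu = 0.20, phi = 0.19, tau = 0.14, lam = 0.0),
    mean = c(cc = 4.44, pe = 12.93, npe = 15.07, fms = 3.11),
    sd   = c(cc = 1.03, pe = 3.17,  npe = 4.29,  fms = 1.59))
)

#' Reference groups
#'
#' The eight fitted parameter regimes shipped with the package: the best-fit
#' agent parameters, the behavioural profile (mean and SD of the four
#' indices) of the corresponding best-fitting model sample, and the human
#' group sizes they were fitted at.  The control-children sample size is
#' reported inconsistently in the source material (52 in the text, 42 in its
#' demographics table); the text value is used and the alternate kept in
#' `n_alt`.
#'
#' @param label Optional group label, e.g. `"asc_teenagers"`; see
#'   `wcst_reference_groups()$label` for all eight.
#' @return `wcst_reference_groups()`: a data frame with one row per group
#'   (label, condition, age, n, n_alt, the four parameters, and the profile
#'   means/SDs).  `wcst_reference_params()`: the group's [wcst_params()].
#'   `wcst_reference_profile()`: the group's [wcst_group_profile()].
#' @examples
#' wcst_reference_groups()[, 1:6]
#' wcst_reference_params("control_teenagers")
#' @export
wcst_reference_groups <- function() {
  rows <- lapply(names(.wcst_reference), function(lab) {
    g <- .wcst_reference[[lab]]
    cbind(data.frame(label = lab, condition = g$condition, age = g$age,
                     n = g$n, n_alt = g$n_alt, stringsAsFactors = FALSE),
          as.data.frame(as.list(g$params)),
          as.data.frame(as.list(stats::setNames(g$mean, paste0(names(g$mean), "_mean")))),
          as.data.frame(as.list(stats::setNames(g$sd, paste0(names(g$sd), "_sd")))))
  })
  do.call(rbind, rows)
}

#' @rdname wcst_reference_groups
#' @export
wcst_reference_params <- function(label) {
  g <- reference_group(label)
  as_wcst_params(g$params)
}

#' @rdname wcst_reference_groups
#' @export
wcst_reference_profile <- function(label) {
  g <- reference_group(label)
  wcst_group_profile(g$mean, g$sd, g$n)
}

reference_group <- function(label) {
  if (!label %in% names(.wcst_reference))
    stop("unknown group '", label, "'; one of: ",
         paste(names(.wcst_reference), collapse = ", "))
  .wcst_reference[[label]]
}

#' Regenerate the reference behavioural profiles
#'
#' Simulates each of the eight reference parameter regimes and compares the
#' simulated index means with the shipped reference profiles, expressing the
#' deviation as a z score against the reference SD (an SD printed as 0 is
#' floored at half the printing resolution, 0.05, for the comparison).
#'
#' @param n Sessions per group; `NULL` (default) uses each group's reference
#'   sample size.
#' @param seed Master seed; group seeds are drawn from it.
#' @return A data frame of class `"wcst_reproduction"`: one row per group and
#'   index with simulated mean/SD, reference mean/SD, z score, and an
#'   `agrees` flag (|z| <= 1).
#' @examples
#' \donttest{rep <- wcst_reproduce(n = 50, seed = 1)}
#' @export
wcst_reproduce <- function(n = NULL, seed = NULL) {
  labs <- names(.wcst_reference)
  if (!is.null(seed)) set.seed(as.integer(seed))
  group_seeds <- sample.int(.Machine$integer.max, length(labs))
  rows <- list()
  for (i in seq_along(labs)) {
    g <- .wcst_reference[[labs[i]]]
    ni <- if (is.null(n)) g$n else as.integer(n)
    sim <- wcst_simulate_group(as_wcst_params(g$params), n = ni,
                               seed = group_seeds[i])
    tol <- pmax(g$sd, 0.05)
    rows[[i]] <- data.frame(
      label = labs[i], index = names(g$mean), n = ni,
      simulated_mean = unname(sim$mean), simulated_sd = unname(sim$sd),
      reference_mean = unname(g$mean), reference_sd = unname(g$sd),
      z = unname((sim$mean - g$mean) / tol),
      agrees = unname(abs(sim$mean - g$mean) <= tol),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wcst_reproduction", "data.frame")
  out
}

#' @export
print.wcst_reproduction <- function(x, ...) {
  y <- as.data.frame(x)
  for (k in c("simulated_mean", "simulated_sd", "z")) y[[k]] <- round(y[[k]], 2)
  print(y, row.names = FALSE)
  cat(sprintf("\n%d of %d index means within one reference SD\n",
              sum(x$agrees), nrow(x)))
  invisible(x)
}
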