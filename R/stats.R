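#' Group-level statistical contrasts
#'
#' The three families of contrasts used to compare fitted model groups:
#' within-group PE-vs-NPE imbalance, one-way ANOVA across the four age
#' groups of a condition with post-hoc pairwise tests, and control-vs-ASC
#' contrasts per age and index.  All t-tests are Welch (unequal variances),
#' two-sided, with Bonferroni correction `p_adj = min(1, m * p_raw)` where
#' the family size `m` is an explicit, documented argument.
#'
#' Degenerate samples (zero variance in both groups) leave the t statistic
#' undefined; such contrasts fall back to an exact equality check, reporting
#' `p = 1` when the group means coincide and `p = 0` otherwise, and are
#' flagged in the `degenerate` column.
#'
#' @return A data frame of class `"wcst_tests"` with one row per contrast and
#'   columns `contrast`, `index`, `statistic`, `df`, `p_raw`, `p_adjusted`,
#'   `band` (`ns`, `<0.05`, `<0.01`, `<0.001`), `significant`, `degenerate`.
#' @name group-stats
NULL

welch_row <- function(contrast, index, x, y, family, alpha) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 sessions")
  degenerate <- var(x) == 0 && var(y) == 0
  if (degenerate) {
    stat <- NA_real_; df <- NA_real_
    p <- if (mean(x) == mean(y)) 1 else 0
  } else {
    tt <- t.test(x, y)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  p_adj <- min(1, family * p)
  data.frame(contrast = contrast, index = index, statistic = stat, df = df,
             p_raw = p, p_adjusted = p_adj, band = p_band(p_adj),
             significant = p_adj < alpha, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

p_band <- function(p) {
  ifelse(p < 0.001, "<0.001", ifelse(p < 0.01, "<0.01",
         ifelse(p < 0.05, "<0.05", "ns")))
}

as_tests <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("wcst_tests", "data.frame")
  df
}

#' @export
print.wcst_tests <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$statistic <- round(y$statistic, 2)
  y$df <- round(y$df, 1)
  y$p_raw <- signif(y$p_raw, digits)
  y$p_adjusted <- signif(y$p_adjusted, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @describeIn group-stats Welch t-test between the per-session PE and NPE
#'   counts of one group.  The default Bonferroni family is the eight fitted
#'   groups.
#' @param group A [wcst_simulate_group()] result (or an n x 4 index matrix).
#' @param family Bonferroni family size.
#' @param alpha Significance level applied to the adjusted p value.
#' @param label Contrast label used in the report.
#' @export
wcst_pe_npe_test <- function(group, family = 8, alpha = 0.05,
                             label = "PE vs NPE") {
  m <- profile_matrix(group)
  as_tests(welch_row(label, "pe-npe", m[, "pe"], m[, "npe"], family, alpha))
}

#' @describeIn group-stats One-way ANOVA on one behavioural index across
#'   (age) groups; when the ANOVA is significant at `alpha`, all pairwise
#'   Welch post-hoc tests are run with Bonferroni family equal to the number
#'   of pairs (6 for four groups).
#' @param groups Named list of groups (each as in `group`).
#' @param index One of `"cc"`, `"pe"`, `"npe"`, `"fms"`.
#' @export
wcst_age_anova <- function(groups, index = c("cc", "pe", "npe", "fms"),
                           alpha = 0.05) {
  index <- match.arg(index)
  stopifnot(length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- lapply(groups, function(g) profile_matrix(g)[, index])
  dat <- data.frame(y = unlist(values, use.names = FALSE),
                    g = factor(rep(names(groups), lengths(values)),
                               levels = names(groups)))
  if (var(dat$y) == 0) {
    anova_row <- data.frame(contrast = "ANOVA", index = index,
                            statistic = 0, df = NA_real_, p_raw = 1,
                            p_adjusted = 1, band = "ns", significant = FALSE,
                            degenerate = TRUE, stringsAsFactors = FALSE)
  } else {
    fit <- aov(y ~ g, data = dat)
    s <- summary(fit)[[1]]
    f <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
    anova_row <- data.frame(contrast = "ANOVA", index = index, statistic = f,
                            df = s[["Df"]][1], p_raw = p,
                            p_adjusted = p, band = p_band(p),
                            significant = p < alpha, degenerate = FALSE,
                            stringsAsFactors = FALSE)
  }
  rows <- list(anova_row)
  if (anova_row$significant) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    for (pr in pairs)
      rows[[length(rows) + 1L]] <-
        welch_row(paste(pr[1], "vs", pr[2]), index,
                  values[[pr[1]]], values[[pr[2]]],
                  family = length(pairs), alpha = alpha)
  }
  as_tests(do.call(rbind, rows))
}

#' @describeIn group-stats Welch t-tests between a control and an ASC group
#'   on each behavioural index, Bonferroni-corrected within the age
#'   (default family: the four indices).
#' @param control,asc The two groups being contrasted.
#' @param indices Indices to test.
#' @export
wcst_condition_test <- function(control, asc,
                                indices = c("cc", "pe", "npe", "fms"),
                                family = length(indices), alpha = 0.05,
                                label = "control vs ASC") {
  mc <- profile_matrix(control)
  ma <- profile_matrix(asc)
  rows <- lapply(indices, function(k)
    welch_row(label, k, mc[, k], ma[, k], family, alpha))
  as_tests(do.call(rbind, rows))
}
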