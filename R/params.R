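#' Agent parameters
#'
#' Bundles the four free parameters of the WCST agent.  Together they fix how
#' the rule priorities held in working memory evolve from trial to trial and
#' how a priority vector is converted into a rule choice.
#'
#' @param mu Error sensitivity in `[0, 1]`: magnitude of the motivational
#'   (reinforcement-learning) update of the selected rule's priority,
#'   downward after negative feedback and upward after positive feedback.
#' @param phi Memory refresh / forgetting speed in `[0, 1]`: fraction of the
#'   distance to the baseline that every priority loses per trial.
#' @param tau Distractibility / explorative tendency in `(0, 1]`: temperature
#'   of the softmax that turns priorities into selection probabilities.
#' @param lam Inner-speech contribution in `[0, 1]`: magnitude of the
#'   feedback-valenced bias re-asserting the selected rule's priority after
#'   decay.  `lam = 0` silences the component.
#'
#' @return An object of class `"wcst_params"`: a named numeric vector
#'   `c(mu, phi, tau, lam)`.
#' @examples
#' wcst_params(0.17, 0.09, 0.12, 0.23)
#' @export
wcst_params <- function(mu, phi, tau, lam) {
  p <- c(mu = as.numeric(mu), phi = as.numeric(phi),
         tau = as.numeric(tau), lam = as.numeric(lam))
  if (anyNA(p) || length(p) != 4L)
    stop("mu, phi, tau and lam must each be a single non-missing number")
  chk <- function(name, lo, hi, lo_open = FALSE) {
    v <- p[[name]]
    bad <- if (lo_open) v <= lo || v > hi else v < lo || v > hi
    if (bad)
      stop(sprintf("parameter '%s' = %g outside %s%g, %g]", name, v,
                   if (lo_open) "(" else "[", lo, hi), call. = FALSE)
  }
  chk("mu", 0, 1)
  chk("phi", 0, 1)
  chk("tau", 0, 1, lo_open = TRUE)
  chk("lam", 0, 1)
  structure(p, class = "wcst_params")
}

#' @export
print.wcst_params <- function(x, digits = 3, ...) {
  cat("WCST agent parameters\n")
  cat(sprintf("  mu  (error sensitivity)      %s\n", format(x[["mu"]], digits = digits)))
  cat(sprintf("  phi (memory decay speed)     %s\n", format(x[["phi"]], digits = digits)))
  cat(sprintf("  tau (softmax temperature)    %s\n", format(x[["tau"]], digits = digits)))
  cat(sprintf("  lam (inner-speech bias)      %s\n", format(x[["lam"]], digits = digits)))
  invisible(x)
}

as_wcst_params <- function(x) {
  if (inherits(x, "wcst_params")) return(x)
  x <- unlist(x)
  if (!all(c("mu", "phi", "tau", "lam") %in% names(x)))
    stop("parameters must be a wcst_params object or named vector/list with mu, phi, tau, lam")
  wcst_params(x[["mu"]], x[["phi"]], x[["tau"]], x[["lam"]])
}

#' Working-memory update primitives
#'
#' The three per-trial updates applied to the vector of rule priorities, in
#' the order they occur inside a trial: the motivational update driven by
#' feedback, the passive decay towards baseline, and the inner-speech bias.
#' Each returns the updated priority vector, clipped to `[0, 1]`.
#'
#' @param wm Numeric vector of three rule priorities in `[0, 1]`.
#' @param phi,mu,lam The parameter governing each update, see [wcst_params()].
#' @param rule Index (1-3) or name of the selected rule.
#' @param positive Logical, the feedback received for that selection.
#' @param baseline Resting priority the decay pulls towards.
#'
#' @return The updated priority vector.
#' @examples
#' wcst_decay(c(0.9, 0.5, 0.5), phi = 0.5)        # 0.7 0.5 0.5
#' wcst_motivational_update(c(0.5, 0.5, 0.5), 1, positive = FALSE, mu = 0.11)
#' wcst_inner_speech_update(c(0.5, 0.5, 0.5), 1, positive = TRUE, lam = 0.23)
#' @name wm-updates
NULL

#' @rdname wm-updates
#' @export
wcst_decay <- function(wm, phi, baseline = 0.5) {
  stopifnot(length(wm) == 3L, phi >= 0, phi <= 1)
  wm + phi * (baseline - wm)
}

#' @rdname wm-updates
#' @export
wcst_motivational_update <- function(wm, rule, positive, mu) {
  stopifnot(length(wm) == 3L, mu >= 0, mu <= 1)
  rule <- match_rule(rule)
  wm[rule] <- clip01(wm[rule] + if (positive) mu else -mu)
  wm
}

#' @rdname wm-updates
#' @export
wcst_inner_speech_update <- function(wm, rule, positive, lam) {
  stopifnot(length(wm) == 3L, lam >= 0, lam <= 1)
  rule <- match_rule(rule)
  wm[rule] <- clip01(wm[rule] + if (positive) lam else -lam)
  wm
}

#' Softmax rule-selection probabilities
#'
#' Probability of selecting each sorting rule given the current working-memory
#' priorities, `p_i = exp(w_i / tau) / sum_j exp(w_j / tau)`.
#'
#' @param wm Numeric vector of three rule priorities.
#' @param tau Softmax temperature, strictly positive.
#' @return Named numeric vector of three probabilities summing to one.
#' @examples
#' wcst_softmax(c(0.8, 0.5, 0.5), tau = 0.12)
#' @export
wcst_softmax <- function(wm, tau) {
  stopifnot(length(wm) == 3L)
  if (!is.numeric(tau) || tau <= 0)
    stop("tau must be strictly positive; use a small tau for near-greedy selection")
  w <- exp((wm - max(wm)) / tau)
  stats::setNames(w / sum(w), .wcst_rules)
}

clip01 <- function(x) pmin(1, pmax(0, x))

match_rule <- function(rule) {
  if (is.character(rule)) rule <- match(rule, .wcst_rules)
  rule <- as.integer(rule)
  if (is.na(rule) || rule < 1L || rule > 3L)
    stop("rule must be 1..3 or one of ", paste(.wcst_rules, collapse = ", "))
  rule
}
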