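#' Simulate one WCST session
#'
#' Plays a full task (at most 128 cards, terminating at six completed
#' categories) with the four-parameter agent.  Within each trial the agent
#' selects a rule by softmax over its working-memory priorities, places the
#' card, receives feedback, and then updates the priorities: the motivational
#' update (`+mu` on positive, `-mu` on negative feedback, on the selected
#' rule), the decay of all priorities towards the baseline at speed `phi`,
#' and finally the inner-speech bias (`+lam`/`-lam` on the selected rule).
#' Applying the inner-speech bias after the decay is what lets it compensate
#' a fast-forgetting working memory.  Priorities are clipped to `[0, 1]`
#' after every update; rule selection is the only stochastic step and
#' consumes exactly one uniform variate per trial.
#'
#' @param params A [wcst_params()] object (or coercible named vector).
#' @param seed Integer seed; the session is a deterministic function of
#'   `(params, seed)`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation built on [wcst_task()] and the update primitives).  Both
#'   engines consume the RNG stream identically and produce identical
#'   sessions.
#' @param baseline Resting priority (default 0.5); initial priorities start
#'   at the baseline.
#'
#' @return An object of class `"wcst_session"`: a list with `profile` (the
#'   four indices, see [wcst_score()]), `trials` (the per-trial log),
#'   `trace` (trials x 3 matrix of priorities as seen by the selector),
#'   `params` and `seed`.
#' @examples
#' s <- wcst_session(wcst_params(0.17, 0.09, 0.12, 0.23), seed = 1)
#' s$profile
#' @export
wcst_session <- function(params, seed = NULL, engine = c("cpp", "r"),
                         baseline = 0.5) {
  params <- as_wcst_params(params)
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(as.integer(seed))
  raw <- if (engine == "cpp") {
    .cpp_session(params[["mu"]], params[["phi"]], params[["tau"]],
                 params[["lam"]], baseline = baseline)
  } else {
    r_session(params, baseline = baseline)
  }
  trials <- data.frame(
    trial = seq_len(raw$n_trials),
    colour = .wcst_levels$colour[raw$cards[, 1]],
    shape = .wcst_levels$shape[raw$cards[, 2]],
    size = .wcst_levels$size[raw$cards[, 3]],
    rule_in_play = .wcst_rules[raw$rule_in_play],
    selected_rule = .wcst_rules[raw$selected],
    chosen_target = raw$chosen_target,
    feedback = ifelse(raw$positive, "positive", "negative"),
    classification = c("CR", "PE", "NPE")[raw$classification],
    fms_flag = as.logical(raw$fms_flag),
    stringsAsFactors = FALSE
  )
  trace <- raw$trace
  colnames(trace) <- .wcst_rules
  structure(list(profile = wcst_profile(raw$counts), trials = trials,
                 trace = trace, params = params, seed = seed),
            class = "wcst_session")
}

# Pure-R engine: same dynamics and RNG consumption as the compiled one.
# Kept as an executable specification of the trial loop; the test suite
# asserts trial-by-trial equality of the two engines.
r_session <- function(params, baseline = 0.5) {
  task <- wcst_task()  # deck shuffled from the current RNG stream
  n_max <- nrow(task$deck)
  p <- rep(baseline, 3)
  cards <- matrix(0L, n_max, 3)
  rule_in_play <- selected <- chosen <- classification <- integer(n_max)
  positive <- fms_flag <- logical(n_max)
  trace <- matrix(NA_real_, n_max, 3)
  counts <- c(cc = 0L, pe = 0L, npe = 0L, fms = 0L)
  t <- 0L
  while (!task$terminated) {
    t <- t + 1L
    trace[t, ] <- p
    rule_in_play[t] <- task$current_rule
    w <- exp((p - max(p)) / params[["tau"]])
    u <- runif(1) * ((w[1] + w[2]) + w[3])
    sel <- if (u <= w[1]) 1L else if (u <= w[1] + w[2]) 2L else 3L
    step <- wcst_step(task, sel)
    task <- step$task
    rec <- step$record
    pos <- rec$feedback == "positive"
    p <- wcst_motivational_update(p, sel, pos, params[["mu"]])
    p <- wcst_decay(p, params[["phi"]], baseline)
    p <- wcst_inner_speech_update(p, sel, pos, params[["lam"]])
    cards[t, ] <- encode_card(c(rec$colour, rec$shape, rec$size))
    selected[t] <- sel
    chosen[t] <- rec$chosen_target
    positive[t] <- pos
    classification[t] <- match(rec$classification, c("CR", "PE", "NPE"))
    fms_flag[t] <- rec$fms_flag
    if (!pos) {
      if (rec$classification == "PE") counts[["pe"]] <- counts[["pe"]] + 1L
      else counts[["npe"]] <- counts[["npe"]] + 1L
      if (rec$fms_flag) counts[["fms"]] <- counts[["fms"]] + 1L
    }
  }
  counts[["cc"]] <- task$completed_categories
  keep <- seq_len(t)
  list(cards = cards[keep, , drop = FALSE], rule_in_play = rule_in_play[keep],
       selected = selected[keep], chosen_target = chosen[keep],
       positive = positive[keep], classification = classification[keep],
       fms_flag = fms_flag[keep], trace = trace[keep, , drop = FALSE],
       counts = counts, n_trials = t)
}

#' @export
print.wcst_session <- function(x, ...) {
  cat(sprintf("WCST session (%d trials%s)\n", nrow(x$trials),
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  print(x$params)
  print(x$profile)
  invisible(x)
}

#' @export
as.data.frame.wcst_session <- function(x, ...) x$trials

#' Plot the working-memory trace of a session
#'
#' Line plot of the three rule priorities across trials, with error trials
#' annotated along the top margin (PE, NPE, and failures to maintain set).
#'
#' @param x A [wcst_session()] object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.wcst_session <- function(x, ...) {
  tr <- x$trace
  matplot(seq_len(nrow(tr)), tr, type = "l", lty = c(1, 2, 1),
          col = c("red3", "blue3", "goldenrod2"), lwd = c(2, 1.5, 1.5),
          xlab = "trial", ylab = "rule priority", ylim = c(0, 1.12),
          main = "Working-memory rule priorities", ...)
  err <- x$trials$classification != "CR"
  if (any(err)) {
    cls <- x$trials$classification[err]
    pch <- ifelse(x$trials$fms_flag[err], 8, ifelse(cls == "PE", 17, 1))
    points(which(err), rep(1.08, sum(err)), pch = pch, cex = 0.7,
           col = ifelse(cls == "PE", "red3", "grey30"))
  }
  legend("bottomleft", bty = "n", cex = 0.8,
         legend = c("colour", "shape", "size", "PE", "NPE", "FMS"),
         col = c("red3", "blue3", "goldenrod2", "red3", "grey30", "grey30"),
         lty = c(1, 2, 1, NA, NA, NA), pch = c(NA, NA, NA, 17, 1, 8))
  invisible(x)
}
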