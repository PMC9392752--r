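#' The four target cards
#'
#' Fixed key cards of the simulated task.  Each attribute value appears on
#' exactly one target, mirroring the standard WCST key-card property, so for
#' any deck card and any sorting rule there is exactly one matching target.
#'
#' @return A 4 x 3 integer matrix (targets x categories) of attribute codes
#'   1-4, with dimnames giving the attribute labels.
#' @examples
#' wcst_targets()
#' @export
wcst_targets <- function() {
  m <- cbind(colour = 1:4, shape = 1:4, size = 1:4)
  rownames(m) <- c("red_triangle_small", "green_circle_medium_small",
                   "blue_square_medium_large", "yellow_bar_large")
  m
}

#' Matching target for each sorting rule
#'
#' For a deck card, the index of the target card sharing the card's attribute
#' on each category.  Uniqueness is guaranteed by the target-card layout.
#' A card identical to a target maps all three rules to that target; cards
#' sharing two attribute values with one target are ambiguous between the two
#' corresponding rules, which is what makes "lucky matches" possible.
#'
#' @param card Integer vector of three attribute codes (colour, shape, size),
#'   each in 1-4, or a character vector of attribute labels.
#' @return Named integer vector: target index (1-4) for each rule.
#' @examples
#' wcst_target_for(c(1, 2, 4))  # red circle large
#' @export
wcst_target_for <- function(card) {
  card <- encode_card(card)
  # target v displays attribute value v on every category
  stats::setNames(as.integer(card), .wcst_rules)
}

encode_card <- function(card) {
  if (is.character(card)) {
    stopifnot(length(card) == 3L)
    card <- mapply(function(v, lev) match(v, lev), card, .wcst_levels)
  }
  card <- as.integer(card)
  if (length(card) != 3L || anyNA(card) || any(card < 1L) || any(card > 4L))
    stop("a card is three attribute codes in 1..4 (colour, shape, size)")
  card
}

#' Build a shuffled session deck
#'
#' Concatenates `n_decks` copies of the full-factorial 64-card deck, each
#' independently shuffled.  With the standard two decks the session holds 128
#' cards and every attribute combination occurs exactly twice.
#'
#' @param seed Optional integer seed; when supplied the deck order is
#'   reproducible.
#' @param n_decks Number of 64-card decks (default 2).
#' @return Integer matrix (cards x 3) of attribute codes with columns
#'   `colour`, `shape`, `size`.
#' @examples
#' deck <- wcst_deck(seed = 1)
#' nrow(deck)  # 128
#' @export
wcst_deck <- function(seed = NULL, n_decks = 2L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  full <- card_attributes(0:63)
  do.call(rbind, lapply(seq_len(n_decks), function(i)
    full[fisher_yates(64L), , drop = FALSE]))
}

# card index k (0-based) -> attribute codes; colour varies fastest
card_attributes <- function(k) {
  m <- cbind(colour = k %% 4L, shape = (k %/% 4L) %% 4L, size = (k %/% 16L) %% 4L) + 1L
  m
}

# Fisher-Yates permutation consuming one uniform per swap, identical to the
# shuffle used by the compiled session engine.
fisher_yates <- function(n) {
  idx <- seq_len(n)
  for (i in n:2) {
    j <- floor(runif(1) * i) + 1
    if (j > i) j <- i
    tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
  }
  idx
}

#' Create a task state
#'
#' Initialises the WCST environment: a seeded 128-card deck, the four target
#' cards, and the hidden rule schedule (colour, shape, size, cycling).  The
#' rule changes silently after `criterion` consecutive positive feedbacks and
#' the task terminates after `max_categories` completed categories or when the
#' deck is exhausted.
#'
#' @param seed Integer seed for the deck shuffle.
#' @param n_decks,criterion,max_categories Task constants; defaults give the
#'   standard administration (128 cards, 10-correct criterion, 6 categories).
#' @return An object of class `"wcst_task"`.
#' @examples
#' task <- wcst_task(seed = 7)
#' task$current_rule
#' @export
wcst_task <- function(seed = NULL, n_decks = 2L, criterion = 10L,
                      max_categories = 6L) {
  structure(list(
    deck = wcst_deck(seed, n_decks),
    trial_index = 0L,
    current_rule = 1L,
    previous_rule = NA_integer_,
    previous_selected = NA_integer_,
    consecutive_correct = 0L,
    completed_categories = 0L,
    criterion = as.integer(criterion),
    max_categories = as.integer(max_categories),
    terminated = FALSE
  ), class = "wcst_task")
}

#' @export
print.wcst_task <- function(x, ...) {
  cat(sprintf(
    "WCST task: trial %d/%d, rule '%s', %d/%d categories, run %d%s\n",
    x$trial_index, nrow(x$deck), .wcst_rules[x$current_rule],
    x$completed_categories, x$max_categories, x$consecutive_correct,
    if (x$terminated) " [terminated]" else ""))
  invisible(x)
}

#' Feedback for a placement
#'
#' Positive if and only if the chosen target is the one matching the card on
#' the task's current hidden rule.  A card ambiguous between two categories
#' can therefore yield positive feedback for a wrongly selected rule (a
#' "lucky match").
#'
#' @param task A [wcst_task()] state.
#' @param card Attribute codes of the card placed.
#' @param chosen_target Target index 1-4.
#' @return `"positive"` or `"negative"`.
#' @export
wcst_feedback <- function(task, card, chosen_target) {
  stopifnot(inherits(task, "wcst_task"))
  chosen_target <- as.integer(chosen_target)
  if (is.na(chosen_target) || chosen_target < 1L || chosen_target > 4L)
    stop("chosen_target must be in 1..4")
  ok <- wcst_target_for(card)[[task$current_rule]] == chosen_target
  if (ok) "positive" else "negative"
}

#' Play one trial of the task
#'
#' Draws the next deck card, places it on the target matching the agent's
#' selected rule, scores the outcome and advances the task state (run
#' counter, category completions, hidden-rule schedule, termination).
#'
#' Classification follows the conventions used throughout the package:
#' a positive trial is a correct response (CR); an error repeating the rule
#' selected on the immediately preceding trial is perseverative (PE), any
#' other error is non-perseverative (NPE); an error that *changes* rule after
#' five or more consecutive correct responses within the current category is
#' additionally flagged as a failure to maintain set (FMS).
#'
#' @param task A non-terminated [wcst_task()] state.
#' @param selected_rule The rule the agent sorts by (index or name).
#' @return A list with `record` (one-row data frame: the trial log entry) and
#'   `task` (the advanced state).
#' @export
wcst_step <- function(task, selected_rule) {
  stopifnot(inherits(task, "wcst_task"))
  if (task$terminated)
    stop("cannot advance a terminated task")
  sel <- match_rule(selected_rule)
  t <- task$trial_index + 1L
  card <- task$deck[t, ]
  chosen <- wcst_target_for(card)[[sel]]
  fb <- wcst_feedback(task, card, chosen)
  positive <- fb == "positive"

  if (positive) {
    classification <- "CR"
    fms <- FALSE
    task$consecutive_correct <- task$consecutive_correct + 1L
    if (task$consecutive_correct == task$criterion) {
      task$completed_categories <- task$completed_categories + 1L
      task$previous_rule <- task$current_rule
      task$current_rule <- task$current_rule %% 3L + 1L
      task$consecutive_correct <- 0L
    }
  } else {
    is_pe <- !is.na(task$previous_selected) && sel == task$previous_selected
    classification <- if (is_pe) "PE" else "NPE"
    fms <- task$consecutive_correct >= 5L &&
      !is.na(task$previous_selected) && sel != task$previous_selected
    task$consecutive_correct <- 0L
  }
  task$trial_index <- t
  task$previous_selected <- sel
  task$terminated <- task$completed_categories == task$max_categories ||
    t == nrow(task$deck)

  record <- data.frame(
    trial = t,
    colour = .wcst_levels$colour[card[[1]]],
    shape = .wcst_levels$shape[card[[2]]],
    size = .wcst_levels$size[card[[3]]],
    selected_rule = .wcst_rules[sel],
    chosen_target = chosen,
    feedback = fb,
    classification = classification,
    fms_flag = fms,
    stringsAsFactors = FALSE
  )
  list(record = record, task = task)
}

#' Score a session from its trial log
#'
#' Recomputes the four behavioural indices from logged trials.  Scoring is a
#' pure function of the `selected_rule` and `feedback` columns: completed
#' categories (CC) from runs of ten consecutive positive feedbacks,
#' perseverative errors (PE) as errors repeating the previous trial's
#' selection, non-perseverative errors (NPE) as all other errors, and
#' failures to maintain set (FMS) as errors changing rule after five or more
#' consecutive correct responses within the current category.
#'
#' @param trials Data frame with columns `selected_rule` and `feedback` (or a
#'   [wcst_session()] object, whose log is used).
#' @param criterion Consecutive correct responses completing a category.
#' @return Named integer vector `c(cc, pe, npe, fms)` of class
#'   `"wcst_profile"`.
#' @examples
#' s <- wcst_session(wcst_params(0.17, 0.09, 0.12, 0.23), seed = 1)
#' identical(wcst_score(s$trials), s$profile)
#' @export
wcst_score <- function(trials, criterion = 10L) {
  if (inherits(trials, "wcst_session")) trials <- trials$trials
  n <- nrow(trials)
  cc <- pe <- npe <- fms <- 0L
  if (n > 0L) {
    sel <- match(trials$selected_rule, .wcst_rules)
    if (anyNA(sel)) sel <- as.integer(trials$selected_rule)
    pos <- trials$feedback == "positive" | trials$feedback == TRUE
    run <- 0L
    for (t in seq_len(n)) {
      if (pos[t]) {
        run <- run + 1L
        if (run == criterion) {
          cc <- cc + 1L
          run <- 0L
        }
      } else {
        repeated <- t > 1L && sel[t] == sel[t - 1L]
        if (repeated) pe <- pe + 1L else npe <- npe + 1L
        if (run >= 5L && t > 1L && sel[t] != sel[t - 1L]) fms <- fms + 1L
        run <- 0L
      }
    }
  }
  wcst_profile(c(cc = cc, pe = pe, npe = npe, fms = fms))
}

wcst_profile <- function(x) {
  x <- as.integer(x[c("cc", "pe", "npe", "fms")])
  structure(stats::setNames(x, c("cc", "pe", "npe", "fms")),
            class = "wcst_profile")
}

#' @export
print.wcst_profile <- function(x, ...) {
  cat(sprintf("WCST profile: CC %d, PE %d, NPE %d, FMS %d\n",
              x[["cc"]], x[["pe"]], x[["npe"]], x[["fms"]]))
  invisible(x)
}
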