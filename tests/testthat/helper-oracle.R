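# Brute-force session rescorer, written independently of wcst_score().
# Walks the (selected rule, feedback) sequence keeping explicit per-trial
# bookkeeping vectors rather than streaming counters, so the two
# implementations share no code path.
oracle_score <- function(sel, positive, criterion = 10) {
  n <- length(sel)
  run_before <- integer(n)   # consecutive positives in category before trial t
  completed <- logical(n)    # trial t completed a category
  run <- 0L
  for (t in seq_len(n)) {
    run_before[t] <- run
    if (positive[t]) {
      run <- run + 1L
      if (run == criterion) {
        completed[t] <- TRUE
        run <- 0L
      }
    } else {
      run <- 0L
    }
  }
  err <- !positive
  repeats <- c(FALSE, sel[-1] == sel[-n])[seq_len(n)]
  changes <- c(FALSE, sel[-1] != sel[-n])[seq_len(n)]
  c(cc = sum(completed),
    pe = sum(err & repeats),
    npe = sum(err & !repeats),
    fms = sum(err & changes & run_before >= 5))
}

# A random scripted session: selections and feedbacks with no underlying
# dynamics, exercising the scorer on arbitrary sequences.
random_script <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:128, 1)
  data.frame(
    selected_rule = sample(c("colour", "shape", "size"), n, replace = TRUE),
    feedback = sample(c("positive", "negative"), n, replace = TRUE,
                      prob = c(0.6, 0.4)),
    stringsAsFactors = FALSE)
}

ref_params <- function(label) wcst_reference_params(label)

# Enumeration oracle: probability that a uniformly selected rule places the
# card on the target matching the current rule, averaged over all 64 cards
# and the 3 possible current rules.
chance_correct_rate <- function() {
  cards <- expand.grid(colour = 1:4, shape = 1:4, size = 1:4)
  total <- 0
  for (i in seq_len(nrow(cards))) {
    card <- as.integer(cards[i, ])
    for (cur in 1:3)
      total <- total + mean(card[1:3] == card[cur])
  }
  total / (nrow(cards) * 3)
}
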