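test_that("session deck is two shuffled full-factorial decks, seeded", {
  deck <- wcst_deck(seed = 0)
  expect_equal(nrow(deck), 128)
  combos <- paste(deck[, 1], deck[, 2], deck[, 3])
  expect_true(all(table(combos) == 2))     # every combination exactly twice
  expect_equal(length(unique(combos)), 64)
  # each 64-card half is itself a complete deck
  expect_equal(length(unique(combos[1:64])), 64)
  expect_identical(wcst_deck(seed = 7), wcst_deck(seed = 7))
  expect_false(identical(wcst_deck(seed = 7), wcst_deck(seed = 8)))
})

test_that("every card maps each rule to exactly one target", {
  targets <- wcst_targets()
  cards <- expand.grid(colour = 1:4, shape = 1:4, size = 1:4)
  for (i in seq_len(nrow(cards))) {
    card <- as.integer(cards[i, ])
    got <- wcst_target_for(card)
    expect_named(got, c("colour", "shape", "size"))
    for (r in 1:3) {
      # brute force: the targets sharing the card's attribute on category r
      match_set <- unname(which(targets[, r] == card[r]))
      expect_length(match_set, 1)
      expect_identical(got[[r]], match_set)
    }
  }
})

test_that("target lookup handles labelled and ambiguous cards", {
  # red circle large: colour -> target 1, shape -> target 2, size -> target 4
  expect_identical(wcst_target_for(c("red", "circle", "large")),
                   c(colour = 1L, shape = 2L, size = 4L))
  # a card identical to a target maps all three rules to it
  expect_identical(unname(wcst_target_for(c(2, 2, 2))), rep(2L, 3))
})

test_that("feedback follows the hidden rule, including lucky matches", {
  task <- wcst_task(seed = 1)            # current rule: colour
  expect_identical(wcst_feedback(task, c(1, 2, 3), 1), "positive")
  expect_identical(wcst_feedback(task, c(1, 2, 3), 2), "negative")
  # enumerate ambiguous cards: a wrong rule agreeing with the current rule's
  # target yields positive feedback
  cards <- as.matrix(expand.grid(colour = 1:4, shape = 1:4, size = 1:4))
  lucky <- 0
  for (i in seq_len(nrow(cards))) {
    card <- cards[i, ]
    if (card[2] == card[1]) {            # shape-target equals colour-target
      expect_identical(wcst_feedback(task, card, wcst_target_for(card)[["shape"]]),
                       "positive")
      lucky <- lucky + 1
    }
  }
  expect_equal(lucky, 16)                # 1/4 of the deck is colour/shape ambiguous
})

test_that("category completion, rule schedule and termination", {
  task <- wcst_task(seed = 3)
  # sort ten cards correctly under the colour rule
  for (i in 1:9) {
    task <- wcst_step(task, "colour")$task
    expect_equal(task$completed_categories, 0)
  }
  step10 <- wcst_step(task, "colour")
  task <- step10$task
  expect_identical(step10$record$classification, "CR")
  expect_equal(task$completed_categories, 1)
  expect_equal(task$current_rule, 2L)          # colour -> shape
  expect_equal(task$previous_rule, 1L)
  expect_equal(task$consecutive_correct, 0)

  # 9 correct then an error leaves the category incomplete and resets the run
  for (i in 1:9) task <- wcst_step(task, "shape")$task
  expect_equal(task$consecutive_correct, 9)
  card_next <- task$deck[task$trial_index + 1L, ]
  unambiguous <- which(card_next != card_next[2])   # rules not lucky-matching shape
  expect_gt(length(unambiguous), 0)                 # holds for this fixed deck
  step_err <- wcst_step(task, unambiguous[1])
  expect_identical(step_err$record$feedback, "negative")
  expect_equal(step_err$task$completed_categories, 1)
  expect_equal(step_err$task$consecutive_correct, 0)
})

test_that("six completed categories terminate the task and freeze it", {
  task <- wcst_task(seed = 5)
  rules <- c("colour", "shape", "size")
  for (k in 1:6)
    for (i in 1:10)
      task <- wcst_step(task, rules[(k - 1) %% 3 + 1])$task
  expect_true(task$terminated)
  expect_equal(task$completed_categories, 6)
  expect_equal(task$trial_index, 60)
  expect_error(wcst_step(task, "colour"), "terminated")
})

test_that("scoring matches hand-built sequences and handles degenerate input", {
  # perfect play: 60 correct trials, six categories, no errors
  perfect <- data.frame(selected_rule = rep("colour", 60),
                        feedback = rep("positive", 60))
  expect_identical(unclass(wcst_score(perfect)),
                   c(cc = 6L, pe = 0L, npe = 0L, fms = 0L))
  # no positive feedback: no categories, no failures to maintain set
  hopeless <- data.frame(selected_rule = rep(c("colour", "shape"), 10),
                         feedback = rep("negative", 20))
  prof <- wcst_score(hopeless)
  expect_equal(prof[["cc"]], 0)
  expect_equal(prof[["fms"]], 0)
  expect_equal(prof[["pe"]] + prof[["npe"]], 20)
  # empty log scores zero
  expect_identical(unclass(wcst_score(perfect[0, ])),
                   c(cc = 0L, pe = 0L, npe = 0L, fms = 0L))
})

test_that("error classification follows the repeat/change conventions", {
  # 7 correct on colour, then an error switching to shape: NPE with FMS flag
  sel <- c(rep("colour", 7), "shape")
  fb <- c(rep("positive", 7), "negative")
  prof <- wcst_score(data.frame(selected_rule = sel, feedback = fb))
  expect_identical(unclass(prof), c(cc = 0L, pe = 0L, npe = 1L, fms = 1L))
  # an error repeating the previous trial's selection is perseverative
  sel2 <- c("colour", "colour", "size", "size")
  fb2 <- c("positive", "negative", "negative", "negative")
  prof2 <- wcst_score(data.frame(selected_rule = sel2, feedback = fb2))
  expect_identical(unclass(prof2), c(cc = 0L, pe = 2L, npe = 1L, fms = 0L))
  # a first-trial error cannot be perseverative
  prof3 <- wcst_score(data.frame(selected_rule = "size", feedback = "negative"))
  expect_equal(prof3[["npe"]], 1)
  expect_equal(prof3[["pe"]], 0)
})

test_that("scoring is a pure function of the log and conserves error counts", {
  params <- ref_params("control_middle_adults")
  for (seed in 1:10) {
    s <- wcst_session(params, seed = seed)
    n <- nrow(s$trials)
    expect_lte(n, 128)
    expect_lte(s$profile[["cc"]], 6)
    cls <- table(factor(s$trials$classification, c("CR", "PE", "NPE")))
    expect_equal(sum(cls), n)                        # CR + PE + NPE = trials
    expect_equal(unname(cls[["PE"]]), s$profile[["pe"]])
    expect_equal(unname(cls[["NPE"]]), s$profile[["npe"]])
    expect_equal(s$profile[["pe"]] + s$profile[["npe"]],
                 sum(s$trials$feedback == "negative"))
    # rescoring the log reproduces the live counts bit-exactly
    expect_identical(wcst_score(s$trials), s$profile)
  }
})
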