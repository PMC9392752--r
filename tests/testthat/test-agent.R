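test_that("parameter validation enforces the legal ranges", {
  p <- wcst_params(0.17, 0.09, 0.12, 0.23)
  expect_s3_class(p, "wcst_params")
  expect_equal(unclass(p), c(mu = 0.17, phi = 0.09, tau = 0.12, lam = 0.23))
  expect_error(wcst_params(1.5, 0.5, 0.5, 0.5), "mu")
  expect_error(wcst_params(0.5, -0.1, 0.5, 0.5), "phi")
  expect_error(wcst_params(0.5, 0.5, 0, 0.5), "tau")   # tau strictly positive
  expect_error(wcst_params(0.5, 0.5, 0.5, 2), "lam")
})

test_that("working-memory update primitives match their closed forms", {
  b <- c(0.5, 0.5, 0.5)
  # decay: fixed point at baseline, full refresh at phi = 1, halfway at 0.5
  expect_equal(wcst_decay(b, phi = 0.7), b)
  expect_equal(wcst_decay(c(0.9, 0.1, 0.5), phi = 1), b)
  expect_equal(wcst_decay(c(0.9, 0.5, 0.5), phi = 0.5), c(0.7, 0.5, 0.5))
  # motivational update: null at mu = 0, subtractive on errors, clipped
  expect_equal(wcst_motivational_update(b, 1, positive = FALSE, mu = 0), b)
  expect_equal(wcst_motivational_update(b, 1, positive = FALSE, mu = 0.11),
               c(0.39, 0.5, 0.5))
  expect_equal(wcst_motivational_update(c(0.05, 0.5, 0.5), 1, FALSE, mu = 0.2),
               c(0, 0.5, 0.5))
  expect_equal(wcst_motivational_update(c(0.95, 0.5, 0.5), 1, TRUE, mu = 0.2),
               c(1, 0.5, 0.5))
  # inner speech: ablated at lam = 0, signed by feedback valence, clipped
  expect_equal(wcst_inner_speech_update(b, 2, TRUE, lam = 0), b)
  expect_equal(wcst_inner_speech_update(b, 2, TRUE, lam = 0.23),
               c(0.5, 0.73, 0.5))
  expect_equal(wcst_inner_speech_update(b, 2, FALSE, lam = 0.52),
               c(0.5, 0, 0.5))
})

test_that("softmax selection probabilities and sampler agree", {
  expect_equal(unname(wcst_softmax(c(0.5, 0.5, 0.5), tau = 0.3)), rep(1 / 3, 3))
  # near-greedy limit
  expect_gt(wcst_softmax(c(0.9, 0.1, 0.1), tau = 0.005)[[1]], 1 - 1e-10)
  expect_error(wcst_softmax(c(0.5, 0.5, 0.5), tau = 0), "positive")
  # closed form at (0.8, 0.5, 0.5), tau = 0.12
  w <- exp(c(0.8, 0.5, 0.5) / 0.12)
  expect_equal(unname(wcst_softmax(c(0.8, 0.5, 0.5), 0.12)), w / sum(w))
  # Monte-Carlo check of the compiled sampler against the closed form
  set.seed(99)
  draws <- wcstsim:::.cpp_select_rule(c(0.8, 0.5, 0.5), 0.12, 100000L)
  freq <- tabulate(draws, 3) / 1e5
  expect_equal(freq, unname(wcst_softmax(c(0.8, 0.5, 0.5), 0.12)),
               tolerance = 0.015)
})

test_that("sessions are deterministic and the two engines coincide", {
  cases <- list(ref_params("control_teenagers"), ref_params("asc_children"),
                wcst_params(0.5, 0.5, 0.5, 0.5))
  for (p in cases) {
    a <- wcst_session(p, seed = 11)
    b <- wcst_session(p, seed = 11)
    expect_identical(a$trials, b$trials)
    expect_identical(a$trace, b$trace)
    r <- wcst_session(p, seed = 11, engine = "r")
    expect_identical(a$trials, r$trials)
    expect_equal(a$trace, r$trace, tolerance = 0)
    expect_identical(a$profile, r$profile)
  }
})

test_that("per-trial dynamics recompose from the update primitives", {
  for (label in c("control_children", "asc_young_adults")) {
    params <- ref_params(label)
    s <- wcst_session(params, seed = 21)
    p <- c(0.5, 0.5, 0.5)
    for (t in seq_len(nrow(s$trials))) {
      expect_equal(unname(s$trace[t, ]), p, tolerance = 1e-12)
      sel <- match(s$trials$selected_rule[t], c("colour", "shape", "size"))
      pos <- s$trials$feedback[t] == "positive"
      p <- wcst_motivational_update(p, sel, pos, params[["mu"]])
      p <- wcst_decay(p, params[["phi"]])
      p <- wcst_inner_speech_update(p, sel, pos, params[["lam"]])
    }
  }
})

test_that("priorities stay within [0, 1] under extreme parameters", {
  for (p in list(wcst_params(1, 0.01, 0.05, 1), wcst_params(1, 1, 1, 1),
                 wcst_params(0, 0.99, 0.9, 0))) {
    s <- wcst_session(p, seed = 31)
    expect_true(all(s$trace >= 0 & s$trace <= 1))
  }
})

test_that("null updates with full decay pin the memory to baseline", {
  # with mu = lam = 0 and phi = 1 the trace never leaves the baseline
  s <- wcst_session(wcst_params(0, 1, 0.5, 0), seed = 41)
  expect_true(all(s$trace == 0.5))
})

test_that("a feedback-blind agent performs at the enumerated chance rate", {
  # mu = lam = 0: priorities stay at baseline, selection is uniform; the
  # correct-placement rate equals the card-ambiguity enumeration (1/2)
  expect_equal(chance_correct_rate(), 0.5)
  pos <- 0; tot <- 0
  for (seed in 1:60) {
    s <- wcst_session(wcst_params(0, 0.3, 0.5, 0), seed = seed)
    pos <- pos + sum(s$trials$feedback == "positive")
    tot <- tot + nrow(s$trials)
  }
  expect_equal(pos / tot, 0.5, tolerance = 0.02)
})

test_that("inner speech compensates a fast-decaying working memory", {
  # high decay, moderate noise: adding the inner-speech bias lifts completed
  # categories (one-sided test at alpha = 0.01 over 200 sessions each)
  with_is <- wcst_simulate_group(wcst_params(0.1, 0.9, 0.2, 0.4), 200, seed = 51)
  without <- wcst_simulate_group(wcst_params(0.1, 0.9, 0.2, 0.0), 200, seed = 52)
  tt <- t.test(with_is$profiles[, "cc"], without$profiles[, "cc"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  expect_gt(mean(with_is$profiles[, "cc"]), mean(without$profiles[, "cc"]))
})

test_that("raising the temperature raises non-perseverative errors", {
  base <- ref_params("control_teenagers")
  lo <- wcst_simulate_group(base, 200, seed = 61)
  hi <- wcst_simulate_group(wcst_params(base[["mu"]], base[["phi"]], 0.83,
                                        base[["lam"]]), 200, seed = 62)
  tt <- t.test(hi$profiles[, "npe"], lo$profiles[, "npe"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("lowering error sensitivity raises perseverative errors", {
  base <- ref_params("control_teenagers")
  hi_mu <- wcst_simulate_group(base, 200, seed = 71)
  lo_mu <- wcst_simulate_group(wcst_params(0.02, base[["phi"]], base[["tau"]],
                                           base[["lam"]]), 200, seed = 72)
  tt <- t.test(lo_mu$profiles[, "pe"], hi_mu$profiles[, "pe"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("session objects expose a well-formed log and trace", {
  s <- wcst_session(ref_params("control_teenagers"), seed = 81)
  expect_named(s$trials, c("trial", "colour", "shape", "size", "rule_in_play",
                           "selected_rule", "chosen_target", "feedback",
                           "classification", "fms_flag"))
  expect_equal(nrow(s$trace), nrow(s$trials))
  expect_identical(colnames(s$trace), c("colour", "shape", "size"))
  # fms is flagged only on error trials
  expect_true(all(s$trials$feedback[s$trials$fms_flag] == "negative"))
})
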