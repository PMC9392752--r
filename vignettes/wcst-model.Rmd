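---
title: "The wcstsim model: dynamics, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The wcstsim model: dynamics, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcstsim)
```

This vignette is the package's account of its science: the task and agent
model it implements, the scoring conventions, the choices made where the
design was genuinely open, and what the simulations can and cannot say
about real data.

## The task environment

The simulated Wisconsin Card Sorting Test uses three categories — colour,
shape and size — with four attribute values each (size replaces the
classic number category, and square/bar replace the star/cross shapes; the
substitution leaves the rule-switching structure untouched). A session
deck is two independently shuffled copies of the full-factorial 64-card
deck, 128 cards in all. The four target cards are fixed so that each
attribute value appears on exactly one target:

```{r}
wcst_targets()
```

This is the standard key-card property: every deck card matches exactly one
target under each rule, so placement is a deterministic lookup
(`wcst_target_for()`). A quarter of the deck is ambiguous between any two
given rules (the card's two attributes point at the same target), which is
what makes "lucky matches" — positive feedback for a wrongly selected rule —
possible. Averaged over deck and rules, an agent selecting rules uniformly
at random is correct exactly half the time.

The hidden rule starts at colour and cycles colour → shape → size. After
ten consecutive positive feedbacks a category completes and the rule
advances silently; the session ends at six completed categories or deck
exhaustion. Lucky matches count towards the ten-correct run because the
run is defined on feedback, which is all the participant (or agent) ever
observes. The rule order and the two shuffling choices are conventions the
source material does not pin down; they are fixed here for determinism and
follow the standard administration style.

## Agent dynamics

The agent holds one priority per rule, `w_i ∈ [0, 1]`, starting at the
baseline `b = 0.5`. Per trial:

1. **Selection.** A rule is drawn by softmax with temperature `τ`,
   `P(i) ∝ exp(w_i / τ)`, consuming exactly one uniform variate. `τ = 0`
   is rejected; near-greedy behaviour is obtained with small `τ` (the
   sampling bound used in fitting is `τ ≥ 0.01`).
2. **Placement and feedback.** The card goes on the target matching the
   selected rule; feedback is positive iff that target also matches the
   hidden rule.
3. **Motivational update** (`μ`): `w_sel ← clip(w_sel ± μ)`, up on positive
   and down on negative feedback.
4. **Decay** (`φ`): `w_i ← w_i + φ (b − w_i)` for every rule.
5. **Inner speech** (`λ`): `w_sel ← clip(w_sel ± λ)` with the feedback's
   valence.

All four parameters live in `[0, 1]` (`τ` strictly positive). The update
primitives are exported (`wcst_decay()`, `wcst_motivational_update()`,
`wcst_inner_speech_update()`, `wcst_softmax()`) and the test suite verifies
that the compiled session engine recomposes from them trial by trial.

### Why this order and these forms

The source account of the model gives the *semantics* of the four
parameters — an error-driven motivational magnitude, a decay speed, a
selection temperature, a feedback-valenced inner-speech bias — but not the
update equations. The forms above are the simplest ones consistent with
those semantics (linear decay to baseline, additive signed updates,
Boltzmann softmax on raw priorities), and three structural choices were
resolved by requiring that the eight shipped parameter regimes actually
regenerate their shipped behavioural profiles (`wcst_reproduce()`):

* **The motivational update is symmetric.** With a purely punishing update
  (`−μ` on errors, nothing on success), an agent with `λ = 0` has no way to
  consolidate a working rule: the two shipped regimes with a silent
  inner-speech component would complete essentially no categories, while
  their reference profiles complete five of six. A reinforcement-learning
  component that learns from reward as well as punishment restores this,
  with `μ` setting both magnitudes.
* **The inner-speech bias is applied after the decay.** This is exactly
  what lets inner speech *compensate* a fast-forgetting memory — the
  compensation role attributed to it — and it is what keeps the fitted
  high-`φ` regimes (e.g. `φ = 0.73` with `λ = 0.33`) at their observed
  behavioural ceiling. Applying decay after all updates instead erodes the
  freshest reinforcement and collapses those regimes.
* **Selection sees the end-of-previous-trial priorities.** Equivalently,
  the decay belongs to the inter-trial interval rather than to the moment
  of choice.

Each of these is isolated behind a single primitive so alternates remain a
one-line change.

### Scoring conventions

* **CR/PE/NPE.** A positive trial is a correct response. An error whose
  selected rule repeats the *previous trial's* selection is perseverative;
  any other error (including a first-trial error) is non-perseverative.
  This operationalises "choosing an incorrect previously chosen rule"
  directly on the selection sequence — which the model exposes, making
  Heaton's indirect inference rules unnecessary — and naturally produces
  "distraction-related" perseverative errors in highly distractible
  regimes: a random agent repeats its previous selection a third of the
  time. The alternative convention (perseveration towards the previous
  *category's* rule) cannot reproduce the shipped profiles: the
  fast-decaying children regime completes almost no categories yet its
  reference profile contains ~25 perseverative errors.
* **FMS.** An error that *changes* rule after five or more consecutive
  correct responses within the current (uncompleted) category — a premature
  and incorrect rule change, the standard failure-to-maintain-set notion.
  The run counter resets on errors and at category completion, so each
  broken run is counted once. Under the repeat-PE convention an FMS error
  is always non-perseverative (keeping `PE + NPE` equal to the total error
  count).
* Scoring is a pure function of the `(selected rule, feedback)` sequence:
  `wcst_score()` rescores any trial log bit-exactly to the live session
  counts, and the test suite checks it against an independently written
  rescorer on a thousand random scripts.

## Randomness and reproducibility

One seeded R RNG stream drives everything: the deck shuffles and the
per-trial selection draw. A session is a deterministic function of
`(params, seed)`; groups draw per-session seeds from the master seed
(`sample.int` on the full integer range), and the random search draws its
configurations and per-configuration group seeds the same way, so a fit is
a deterministic function of `(target, n_configs, n_runs, bounds, seed)`.
The compiled and pure-R engines consume the stream identically and are
asserted trial-identical in the tests.

Numerical details: the softmax subtracts the maximum priority before
exponentiating (stable down to `τ = 0.01`); priorities clip to `[0, 1]`
after every update so `τ` keeps a stable meaning across regimes; ranking
ties in the search keep sampling order; group SDs use the population
convention (divide by `n`), chosen once and documented — switching to the
sample convention is a one-line change and does not enter the fitting
objective.

## Fitting and parameter recovery

The search follows the original procedure — vary only the four free
parameters, keep everything else fixed, minimise the MSE over the four
index means. Defaults: 2000 configurations, uniform in the full legal box
(`τ ∈ [0.01, 1]`), `n_runs` equal to the target's sample size. The
objective ignores the target SDs (the simplest reading of an MSE on
indices); with four indices on different scales the error is dominated by
the large-count indices, which is acceptable for ranking but worth knowing
when interpreting MSE values.

Parameter recovery is validated on synthetic targets
(`wcst_synthetic_target()`, 50 sessions per target) generated at
`λ ∈ {0, 0.4}` with `μ = 0.1, φ = 0.9, τ = 0.2`: across ten replicate
searches the refit `λ` orders the two generators correctly in at least
nine. Point identification of `λ` is *not* claimed — a silent inner-speech
profile can be mimicked by other parameter trade-offs, so the recovery
property is ordering, and the recovery tests assert exactly that. Searches
for recovery use 10 sessions per candidate configuration: the targets'
sampling noise dominates the objective at that size, and a 2000-point
search stays within a few seconds.

## What the simulations show — and what they do not

The synthetic-data generator *is* the model: simulations probe the
behaviour of this reconstruction, under symbolic perception (the deck card
and targets are compared exactly; there is no visual front end, no
generative perceptual hierarchy, no saccade/motor variability). The
original architecture performs perceptual matching on generated images, but
its four free parameters do not touch perception, so at the level of the
behavioural indices the symbolic abstraction is equivalent — that
equivalence is an assumption of this package, not a demonstrated result.

The shipped reference regimes (`wcst_reference_groups()`) regenerate their
reference profiles closely but not perfectly: the reproduction report
(`wcst_reproduce()`, also asserted in the acceptance tests at the groups'
sample sizes and at n = 200) shows 29 of 32 index means within one
reference SD, with three systematic, marginal deviations (|z| ≈ 1.0–1.3):
the best-performing control regime makes somewhat too few non-perseverative
errors, the most distractible regime slightly too many, and the regime
shared by two reference groups sits near the upper of their two printed CC
means — those two groups share identical parameters, so no single regime
mean can match both printed values at once. These residuals are the
fidelity limit of reconstructing unpublished update equations from
parameter semantics plus printed profiles; they are reported rather than
tuned away.

Group statistics use Welch two-sided t-tests and classical one-way ANOVA
with explicit Bonferroni families (8 groups for the PE-vs-NPE family, 6
pairs for post-hocs, 4 indices for condition contrasts) — family sizes are
arguments, not constants, because the original analyses report only
significance bands. The PE-vs-NPE contrast is run unpaired even though both
counts come from the same sessions; a paired test would be defensible and
slightly more powerful, but the unpaired Welch test is the conservative
choice when only group summaries are available for comparison. Groups whose
index is constant (e.g. a CC ceiling with SD 0) make the t statistic
undefined; such contrasts fall back to an exact equality check (`p = 1`
when equal, `p = 0` otherwise) and are flagged. Under
identical-generator simulation the corrected condition contrasts keep their
family-wise type-I error at or below 0.05 (asserted over 500 replicate
pairs in the acceptance tests).

Problem sizes used by the test suite — 200 sessions per regime for
signature and reproduction checks, ten replicate 2000-configuration
searches for recovery, 500 replicate pairs for error control — were chosen
as the smallest sizes at which the corresponding statistical assertions are
stable.

## Limitations

* The update equations are a declared reconstruction; quantities that
  depend on fine dynamics (e.g. exact activation traces) are qualitative.
* Fitted parameters describe *group mean* profiles; fitting individual
  sessions would need a likelihood, not an MSE on summary indices.
* `λ` is only weakly identified from behavioural indices alone; claims
  about inner speech rest on ordering and on converging evidence, not on
  point estimates.
* The model omits perception and motor control entirely, and the printed
  reference profiles are themselves model fits to four separate human
  studies, not raw human data.
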