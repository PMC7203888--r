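---
title: "Measuring and decomposing intervention intensity in childbirth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing intervention intensity in childbirth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iatropath)
```

## The model

Labour is treated as a staged process running from onset (`O`) to birth
(`B`), during which a woman may receive interventions from an ordered
*sequential protocol*: less invasive treatments come before more invasive
ones, except for emergencies, which appear as direct transitions that skip
intermediate states.  The default protocol is augmentation (`A`, amniotomy
and/or synthetic oxytocin after the diagnosis of labour onset), ventouse
(`V`) and caesarean section (`C`).  Because augmentation protocols differ
between wards in whether amniotomy precedes oxytocin, the two raw flags are
merged by logical OR into the single augmentation intervention before any
analysis; this is the only preprocessing the package performs on raw
records.

With `n` interventions a woman follows one of the `2^n` binary
*intervention paths* `(x, y, z, ...)`; paths combining ventouse and
caesarean are legitimate (a failed ventouse followed by surgery).  The
universal data structure is the *path-count table*: `N(path)` women per
path, `N` in total.

From a path-count table the package computes the *overall treatment ratio*
`H = E/N` (total treatments per woman, in `[0, n]`) and the *iatrogenic
labour index* `ILI = H/n` in `[0, 1]`, in five algebraically equivalent
forms:

1. `H = S · H_T`: treated proportion times mean treatments among the
   treated;
2. `H = Σ_j H_j`: sum of the *type-specific treatment ratios*
   `H_j = E_j/N`;
3. `H = Σ_i i · f_i`: mean of the distribution of the number of treatments;
4. `H = Σ_path (x+y+z) · f(path)`: path-weighted mean;
5. `H = Σ_j v_j(p)`: a functional of the *progression proportions* of the
   Markov representation (below).

Equivalence of the five forms is an identity, and the test suite checks it
to `1e-12` on a thousand random tables.  All ratios are formed from exact
integer numerators and denominators; rounding happens only in printed
renderings (reports round to three decimals for `H`-like quantities and
one decimal for percentages).

## The Markov representation and its estimator

The compartmental view places each woman in a forward absorbing chain
`O → (A) → (V) → (C) → B`.  Its parameters are the *progression
proportions* `p[s->t]`: the probability that a woman in state `s`
progresses next to treatment `t` rather than to a state in between, with
the remainder `1 − Σ_t p[s->t]` exiting to birth.  The estimator is the
*history-pooled* maximum-likelihood one: women arriving at a state by any
route are pooled in the denominator.  This choice makes the identity
`N · v_j = E_j` exact — the visit probabilities

```
v_j = p[O->j] + Σ_{i<j} v_i · p[i->j]
```

computed by forward recursion reproduce the integer treatment totals of
the table, so Form 5 agrees with Forms 1–4 *exactly*, not just in
expectation.  The recursion is linear in the number of states and is
validated in the tests against exhaustive enumeration of all `2^n` paths
up to `n = 8`.

The Markov property itself — that progression depends only on the current
state, not the route to it — is an empirical hypothesis.
`markov_property_test()` checks it per (state, target) by cross-classifying
the women who reached the state by their history and applying Fisher's
exact test.  Fisher was chosen over the chi-square because the
history-specific cells in cohorts of a few hundred women are tiny (the
reference cohort has 10 and 17 women in the two ventouse histories);
expected counts sit far below chi-square validity thresholds.  No
multiplicity correction is applied by default (few tests are produced for
small `n`); a Bonferroni flag exists for wide protocols.

## Decomposition of a difference between cohorts

Two complementary attributions of `H_2 − H_1` are provided.

*Multiplicative split* (`form1_decompose()`): the relative difference
decomposes exactly as `relS + relH_T + relS · relH_T`, separating "fewer
women treated" from "treated women treated less", plus their interaction.

*Stepwise replacement* (`stepwise_replacement()`): starting from the
cohort-1 progression proportions, each PP is replaced in turn by its
cohort-2 value and the functional (the OTR, a single type-specific ratio,
or an aggregate such as operative delivery `H_V + H_C`) is re-evaluated.
The partial differences sum *exactly* to `H_2 − H_1` for every replacement
order; the endpoints are order-free.  The default order replaces PPs
leading to less invasive treatments first (source state ascending, then
target ascending).  Scaled contributions divide each step by the magnitude
of the first one and multiply by 100, so the first step reads ±100 and the
others are directly comparable to it; they are reported missing when the
first step is exactly zero.  Because the attribution (not the total) is
order-dependent, `order_sensitivity()` enumerates all `k!` orders (or a
seeded sample above `7!`) and reports each PP's min/mean/max partial
difference — the mean over orders being the Shapley attribution.  On the
built-in cohorts the augmentation entry `O->A` dominates every other
contribution in every order.

## Robson reporting and standardization

`robson_report()` derives the four standard percentage columns of a
ten-group report from integer class counts (the vocabulary includes the
IIa/IIb and IVa/IVb onset splits; unknown labels are rejected rather than
coerced, and all derived columns are recomputed from the counts rather
than trusted from input).  `standardized_ratio()` performs *direct*
standardization of any treatment-ratio functional across classes: fixed
reference weights (default: the pooled class distribution of the two
cohorts) applied to class-specific values.  Direct standardization was
chosen as the simplest procedure consistent with fixed-weight
comparability; indirect standardization would need external
class-specific reference rates that a two-cohort comparison does not
supply.

## Cohort comparison tests

`compare_path_distributions()` runs the chi-square test of homogeneity on
the `2 × k` path-count table.  Sparse categories are pooled before
testing: the category with the smallest expected cell is merged into an
`"other"` category until every expected count reaches `min_expected`
(default 5), and each merge is logged in the result for audit.  A
Monte-Carlo p-value is available for tables where even pooling leaves the
asymptotics doubtful.  `compare_proportions()` is the two-sample Pearson
chi-square on a single ratio, without continuity correction by default (a
flag enables Yates); at the cohort sizes of interest the correction does
not change any qualitative conclusion, and the uncorrected statistic
matches the textbook `Σ (O−E)²/E` oracle exactly.

## The synthetic-cohort generator

`simulate_cohort()` draws women through the forward chain itself: one
uniform draw per state visit, vectorised by source state in protocol
order, so a fixed seed reproduces the cohort bit for bit.  The generator's
default conditions are the estimated progression proportions of the
built-in reference cohorts at their real sizes (637 and 1375 women) —
i.e. it emulates a labour ward of that scale, not an idealised large
sample.  What it deliberately does **not** emulate: intervention timing
and sojourn durations, covariates, Robson-class mechanisms (strata are
simulated independently), and calendar drift.  Passing tests therefore
validate the estimators and decompositions under the stated chain model,
not the clinical realism of any particular ward.

*History modifiers* create controlled Markov violations: a modifier
multiplies the odds of one transition for women whose earlier-treatment
flags match a given history, clipped to `[0, 1]`.  Odds-scale
multiplication was chosen so extreme settings remain valid probabilities;
every effective transition distribution is validated over all possible
histories before any sampling.

Numerical experiment sizes used by the validation suite, chosen to give
stable Monte-Carlo behaviour: parameter recovery at `N = 1e5` (each PP
within 3 binomial standard errors of truth); estimator bias over 100
replicates of `N = 1e4`; null calibration of the Fisher-based Markov test
over 200 replicates of `N = 1e5` (empirical size 0.040 against the
nominal 0.05, inside the 3-SE Monte-Carlo band — Fisher's exactness makes
it mildly conservative); null calibration of the homogeneity test over
500 cohort pairs of `N = 5000`.  The power experiment for the Markov test
uses a modifier multiplying the `V->C` odds by 4 for via-augmentation
arrivals at `N = 5000` (measured power 0.88 over 200 replicates): at the
reference-cohort progression proportions only ~130 women per replicate
reach ventouse via augmentation, so milder violations (e.g. odds doubled)
are genuinely hard to detect at realistic ward sizes — a substantive
caveat for users planning such a test, documented rather than hidden by
an inflated simulation size.

## Degenerate inputs and numerical conventions

* `N = 0` tables are representable (an empty ward) but every ratio
  operation raises an error rather than returning `NaN`.
* Progression proportions from never-reached states are *undefined*, kept
  as `NA` with their zero denominators; functionals treat them as zero
  with an explicit warning, so sparse cohorts remain analyzable.
* `H_T` is missing when nobody was treated; scaled stepwise contributions
  are missing when the first partial difference is zero; a Robson class
  with zero women has a missing caesarean rate.
* Ties in the pooling rule are resolved by canonical path order; the
  running `"other"` category is never merged into itself — when it is the
  sparsest, the next-smallest category joins it.
* JSON serialisations use 17 significant digits, so write-then-read
  round-trips reproduce doubles exactly.

## Known limitations

The framework measures *how many* interventions occur, not whether they
were appropriate; it carries no notion of time, so identical paths with
very different labour durations are indistinguishable; variance estimates
and confidence intervals for `H`, the ILI and the stepwise contributions
are not provided; and the Markov test's power at single-ward sample sizes
is modest, as quantified above.
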