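---
title: "An inclusive-fitness game of intergenerational reproductive conflict"
author: "kinconflict authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An inclusive-fitness game of intergenerational reproductive conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinconflict)
```

## The question

Why should losing a parent *accelerate* an adolescent's first birth, when
parental investment is supposed to help offspring? One answer treats the
family as a cooperatively breeding unit whose household resources
(alloparenting, provisioning) limit how many infants can be raised at once.
A parent and her adolescent offspring may then be rivals for the same
reproductive opportunity, and the outcome of that rivalry turns on genetic
relatedness: an adolescent values a full sibling (r = 0.5) as much as her own
child, but a half sibling only as much as her parent values a grandchild
(r = 0.25). Parental death or re-partnering converts future full siblings
into half siblings, strips the parent of her relatedness advantage, and makes
early reproduction relatively more attractive to the adolescent.
`kinconflict` implements this logic as a fully solved two-player game.

## The model and its assumptions

Two actors of reproductive age share a household: the parent G1 and her
adolescent offspring G2. Each chooses to reproduce (R) or not (N), once.
The model deliberately assumes:

* **Household-limited resources.** Only co-residence matters: with two
  infants in the household each survives at ratio `s` ∈ [0, 1] of a sole
  infant's survivorship (sole-infant survivorship is normalised to 1, which
  is what makes `s` a ratio). There are never benefits to sharing.
* **No other strategic actors.** Mates are available at no cost, and the
  interests of the adolescent's partner, the other siblings and any
  stepparent do not enter the payoffs. Household structure enters only
  through the parameters.
* **One decision, no future rounds.** Payoffs are the expected
  inclusive-fitness contribution of the current reproductive bout; there is
  no discounting and no repeated play.
* **Sequential, autonomous decisions.** The two actors decide in sequence
  and the second mover observes the first; nobody can coerce the other.
  Which actor *gets* to move first is contested, and willingness to compete
  for that position is measured by what an actor loses by moving second.
* **Equal competitive ability.** The predicted conflict winner is the actor
  with the larger loss to moving second; the model does not convert losses
  into win probabilities (no tug-of-war effort dynamics).

The three parameters are the survival ratio `s`, the parental continuity
`c` ∈ [0, 1] (probability the parent's next infant is a full sibling of the
adolescent; `c` only affects the adolescent's payoffs), and the youth
benefit `y` > 0 (fitness of the adolescent's infant relative to the
parent's; `y` > 1 is parental reproductive senescence, and values below 1 —
e.g. benefits to the adolescent of further growth or learning — favour the
parent). All three are validated strictly at construction
(`game_params()`); both `y` > 1 and `y` < 1 are legitimate regimes.

The eight conditional payoffs (`payoff()`, `payoff_table()`) weight each
surviving infant by the actor's relatedness to it and by its quality:
`V1(R|R) = 0.5s + 0.25sy`, `V1(R|N) = 0.5`, `V1(N|R) = 0.25y`,
`V2(R|R) = 0.5sy + 0.25s(1+c)`, `V2(R|N) = 0.5y`, `V2(N|R) = 0.25(1+c)`,
and `V(N|N) = 0` for both. At `c = 0`, `y = 1` the two payoff tables
coincide entry for entry: the game is symmetric.

## Solving the game

`best_response()` compares a second mover's two payoffs given the first
mover's action. The four comparisons have closed-form critical survival
ratios (`conflict_thresholds()`): the adolescent adds a second infant when
`s > (1+c)/(2y+1+c)`, the parent when `s > y/(y+2)`, and the first movers
*want* the addition when `s > 2/(y+2)` (parent's wish) or
`s > 2y/(2y+1+c)` (adolescent's wish). `sequential_outcome()` composes a
reproducing first mover with the second mover's best response;
`bruteforce_solve()` is an independent backward-induction oracle that works
from the tabulated payoffs alone, and additionally lets the first mover
optimise its own action — exposing, as `first_mover_abstains`, the region
(e.g. `y > 2` for the parent in zone 1) where even the first mover prefers
to forgo reproducing.

`classify_zone()` orders the two second-mover thresholds into zone
boundaries: zone 1 below both (one reproducer only), zone 2 strictly
between (the infant count depends on move order), zone 3 above both (both
reproduce). Which bound is lower flips at `y = sqrt(1+c)`, where zone 2 is
empty and the actors never disagree about the infant count.

`loss_to_second()` and `predict_winner()` quantify the conflict: an actor's
loss is its payoff moving first minus its payoff when the other moves
first. Losses of 0.25 each at `c = 0`, `y = 1`, `s < 1/3` make the
symmetric game a genuine hawk–dove standoff (reported as a `"tie"`; the
model provides no behavioural tie-break and we do not invent one). At
`c = 1` the adolescent's loss is 0 and the parent wins; for
`y > (3+c)/3` in zone 1 the balance tips to the adolescent. Negative losses
(an actor prefers moving second, typical of zone 2) are reported as
`endogenous_timing`: both players agree who should move first.

Losses follow the reproduce-first convention of the sequential payoff
functions even where an optimising first mover would abstain; the
brute-force solver's abstention flags are exposed alongside, because both
readings of "loss" are informative and they differ only where the flag is
set.

## Numerical conventions

* All "wants to reproduce" conditions are strict inequalities, as in the
  model's derivation. Exact indifference — judged with one package-wide
  absolute tolerance, `kc_tol()`, default 1e-9 and settable via
  `options(kinconflict.tol = )` — resolves to N with a tie flag. This makes
  threshold behaviour exactly testable and is conservative about adding
  infants to the household.
* Zone boundaries are open: a point within tolerance of a bound is assigned
  to the adjacent lower-numbered zone and flagged `on_boundary` (a
  measure-zero set; flagged rather than silently classified, and the CLI
  warns about it).
* Winner ties are declared within the tolerance, never by exact
  floating-point equality.
* `y = sqrt(1+c)` makes the two zone bounds algebraically equal; in floating
  point they agree to about 1e-16, which the tolerance treats as an empty
  zone 2.

## The stochastic household simulator

`simulate_payoffs()` validates the analytic payoffs with a generative model
transcribed from the parameter definitions: each reproducing actor produces
one infant; a sole infant survives with probability 1, while two co-resident
infants survive *independently* with marginal probability `s` each; the
parent's infant is a full sibling of the adolescent with probability `c`
(relatedness 0.5, else 0.25); an actor's realised payoff sums relatedness ×
quality (`y` for the adolescent's infant, 1 for the parent's) over surviving
infants. Averages over replicates are unbiased for the analytic payoffs,
and the result reports standard errors and z-scores.

Two modelling choices deserve note. Survival draws are independent because
the model specifies only marginal survivorship ratios; independence is the
minimal completion (a shared-household-shock correlation would change
nothing analytic, since the payoffs are linear in each infant's marginal
survival, but would change the Monte Carlo variance). Quality `y` is a
deterministic multiplier on a surviving infant's contribution, not a
survival modifier, because the payoffs apply `y` multiplicatively outside
`s`.

The simulator uses R's Mersenne–Twister stream, seeded per call and
restored afterwards, so results are bit-reproducible and the global RNG
state is never consumed. `convergence_report()` tabulates the O(1/sqrt(n))
shrinkage of the estimation error.

What passing simulations do and do not show: they confirm that the analytic
expressions are the correct expectations of the stated generative model;
they say nothing about whether real households have independent infant
survival, one reproductive bout, or payoff-linear relatedness accounting.

## Comparative statics

`absence_effect()` computes the adolescent's add-a-second threshold with
both genetic parents present (`c = 1`: `1/(y+1)`) and with one absent
(`c = 0`: `1/(2y+1)`), and their difference as a percent of the
parent-present value — the *parent-present* threshold is the denominator,
a choice worth stating explicitly because prose descriptions of "percent
difference" are ambiguous. The percent difference is 33.33 % at `y = 1`,
42.86 % at `y = 3`, increases strictly with `y`, and vanishes as `y` tends
to 0: senescence amplifies, and youth costs of early reproduction dampen,
the predicted parental-absence effect.

`family_structure_params()` maps four stylised household structures to
parental continuity plus two qualitative flags (non-kin presence, parental
mate-search costs) and an ordinal age-at-first-birth prediction. The
qualitative values "~1" and "> 0" are mapped to overridable defaults 1.0
(two genetic parents) and 0.5 (other single parent); the flags are carried
as metadata only, since the model never formalises mate-search costs or a
stepparent's interests. `afb_rank_consistency()` checks the ordinal
prediction against the model itself, using the adolescent's loss-to-second
as the proxy for early-reproduction pressure; the two intermediate-ranked
structures are deliberately not ordered against each other, and the check
refuses to run where no conflict exists (zone 3).

`conflict_sweep()` and the `fig1_data()` / `fig2_data()` / `fig3_data()`
helpers generate the tidy tables behind the model's three canonical
displays (threshold curves over `c`, loss profiles over `s`, absence-effect
curves over `y`). The loss-profile panels cross `c` ∈ {0.25, 1} with
`y` ∈ {0.3, 1, sqrt(1+c), 3} and are lettered A–H column-major over `c`; the
lettering is this package's own convention, and panels can equally be
selected by their `(c, y_label)` pair. All figure data are deterministic;
the only randomness anywhere in the package is in the simulator.

## Problem sizes used in the checks

The test suite solves the game exactly, so most checks are instantaneous
desk-scale evaluations. The property-style suites use 10,000 random
parameter draws for the oracle-equivalence check, bisection to 2^-60 for
threshold consistency, a 27-cell (s, c, y) design at 100,000 replicates per
cell for Monte Carlo recovery (3-standard-error bands), and 100 cells at
10,000 replicates for z-score calibration — sizes chosen so the whole suite
solves in minutes on one core while keeping Monte Carlo bands a couple of
orders of magnitude tighter than the effects being checked.

## Known limitations

* The model predicts the *likely winner*, not win probabilities or effort
  expenditure; mapping losses to contest outcomes needs a tug-of-war model.
* Mixed strategies of the simultaneous hawk–dove game are out of scope; play
  is sequential by assumption.
* The symmetric game's tie has no behavioural resolution.
* Mate-search costs, stepparent interests, sex differences, and cultural
  institutions enter only as user-supplied effective `c` or `y` values, not
  as model structure.
* Payoffs are single-bout and undiscounted; there is no demography, no
  senescence evolution, and no population feedback.
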