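---
title: "Social information use under variable resources: model and methods"
author: "socialforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social information use under variable resources: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialforage)
```

## The question

Foragers can learn where food is by sampling the environment themselves
(personal information) or by watching conspecifics (social information).
Social information is cheap but can mislead: followers end up sharing
patches with the individuals they copied, so its value depends on how
resources are distributed. `socialforage` implements two connected pieces:

1. an **agent-based evolutionary simulation** asking when a
   social-learning strategy outcompetes an individual-learning strategy as
   a function of resource variance between patches, and
2. an **analysis pipeline for two-by-two bee choice experiments** (cue
   type x prior reward distribution) of the kind used to test that
   prediction with bumblebee foragers, together with a synthetic-data
   generator that makes the pipeline testable end to end.

## The simulation model

A constant population of `n_agents` foragers feeds on `n_patches` patches.
Every time step a total of `total_resource` units (R) is distributed over
patches:

* **no-variance world** — every patch holds `R / n_patches`, constant over
  time;
* **high-variance world** — `n_rich_patches` patches drawn uniformly at
  random hold `R / n_rich_patches` each and all others hold nothing; the
  rich set is redrawn every `turnover_interval` steps.

Each agent keeps a memory vector: its current estimate of per-capita
intake on every patch. Each step it visits the patch with the highest
estimate (ties broken uniformly at random), except that with probability
`explore_prob` it samples a uniformly random patch instead. All occupants
of a patch split its payoff equally — exploitative competition — and the
realised per-capita intake accrues to lifetime fitness.

Learning differs between the two heritable strategies. *Individual
learners* overwrite the memory entry of the patch they visited with the
intake they just experienced. *Social learners* do the same **and**
additionally observe one other forager chosen uniformly at random,
overwriting the entry for that forager's patch with that forager's
realised intake. Observation is free and happens after all foraging in
the step is resolved.

Selection acts by death and replacement: each agent dies with probability
`death_rate` per step, and each vacancy is filled by an offspring of a
surviving parent drawn with probability proportional to accumulated
fitness (uniformly if all survivor fitnesses are zero; from the pre-death
population if everybody died). Newborns start with zero fitness, a flat
memory at `memory_init`, and flip strategy with probability
`mutation_prob`. The replicate-level outcome is the *evolved proportion of
social learners*: the population proportion averaged over the final
`1 - burn_in_fraction` of steps.

### Modelling choices that were genuinely open

* **Memory is full replacement**, not exponential smoothing: the simplest
  rule under which a single visit reveals both profitability and
  depletion. A learning-rate parameter would add a dimension without
  changing the qualitative contrast.
* **Social learners also record their own intake.** Pure observers that
  ignore their own experience starve under competition (they can never
  learn that the patch they crowd onto pays little), which makes the
  strategy degenerate rather than interestingly inferior.
* **Fitness-proportional (roulette) selection over survivors** rather
  than strict best-of-population copying: copying the argmax makes
  evolution nearly deterministic and brittle; roulette is the standard
  stochastic reading of "offspring of the most successful foragers".
* **Within-step order is fixed**: payoff redraw, patch choice, sharing,
  fitness accrual, memory updates (own experience, then observation),
  mortality. Reordering these changes the dynamics, so the order is part
  of the model definition, not an implementation detail.
* **Newborns do not inherit parental memory**: strategy is the only
  heritable trait, keeping the two strategies symmetric in everything
  except how they acquire information.

### Default parameters and how they were chosen

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `n_patches` | 40 | patches | see calibration below |
| `n_agents` | 50 | foragers | moderate drift, cheap to run |
| `total_resource` | 100 | resource units / step | sets the scale only |
| `n_rich_patches` | 1 | patches | see calibration below |
| `turnover_interval` | 10 | steps | rich patches persist but not long |
| `explore_prob` | 0.05 | probability / step | rare undirected sampling |
| `death_rate` | 0.05 | probability / step | ~20-step lifetimes, ~250 generations per replicate |
| `mutation_prob` | 0.02 | probability / birth | keeps both strategies present |
| `initial_social_fraction` | 0.5 | proportion | uninformative start |
| `n_steps` | 5000 | steps | long past the transient |
| `burn_in_fraction` | 0.8 | proportion | average the final 1000 steps |
| `memory_init` | 0 | intake units | naive agents choose at random |

The qualitative contrast — social learning wins under high variance, loses
under no variance — is robust over a wide parameter range, but the
quantitative equilibria are not pinned down by theory, so the defaults
were calibrated once against the reference behaviour of this class of
model (evolved proportion of social learners near 0.96 under high
variance, near 0.2 under no variance, with replicate-to-replicate
standard deviations near 0.02 and 0.2 respectively). The mechanics behind
the calibration:

* The social advantage under high variance is governed by the ratio of
  *individual search time* to *turnover period*. With 40 patches and one
  rich patch, blind rediscovery takes ~40 steps of random sampling while
  the rich set turns over every 10 steps, so individual learners spend
  most of their time searching; social observation propagates the
  location in a few steps. Spreading the same resource over 12 patches
  with 2 rich ones (a geometry that mirrors the companion flower array)
  makes individual search fast enough that the social advantage shrinks
  and the equilibrium drops to ~0.5.
* The social *disadvantage* under no variance is a crowding penalty:
  observers are drawn to patches that are already occupied even though
  all patches pay alike, so they systematically share more. With 40
  patches for 50 agents this penalty is mild, and the no-variance
  equilibrium settles at the mutation-drift floor near 0.2 with large
  between-replicate drift (the trait is nearly neutral there).
* `mutation_prob = 0.02` sets that floor; halving it roughly halves the
  no-variance mean without materially moving the high-variance one.

The regime contrast itself (ordering plus non-overlapping confidence
intervals) does not depend on this calibration; only the two point values
do.

### Numerical and degenerate-input behaviour

Patch payoffs always sum to `total_resource` exactly; per-step population
intake equals the summed payoff of *occupied* patches (unoccupied payoff
is wasted, never banked) and is checked to 1e-9 in the tests. Argmax ties
in patch choice are broken uniformly at random to avoid positional
artifacts — in particular, naive agents with flat memory choose uniformly.
`high_variance` with `n_rich_patches == n_patches` is numerically
identical to `no_variance`. A population of one social learner simply has
nobody to observe; `death_rate = 0` freezes the strategy composition
exactly; `n_patches = 1` makes information worthless and the strategies
selectively neutral, which is used as a drift null in the tests.

Each replicate runs on R's generator from a single integer seed;
experiment replicates derive their seeds from a master seed by fixed
increments, so summaries are bit-reproducible and independent of
execution order.

## The choice-experiment pipeline

The empirical design the pipeline (and generator) targets: foragers are
trained with either a *social* cue (a bee-mimicking model on the flower)
or a visually matched *non-social* cue, and experience either a
*high-variance* reward distribution (all sucrose concentrated on two
flowers) or a *no-variance* one (sucrose spread over all flowers). At
test, 4 of 12 flowers carry the familiar cue and the outcome is whether a
bee's **first landing** is on a cued flower; chance is therefore
`chance_level()` = 4/12 = 1/3. During cue training, cues are imperfectly
reliable (2 of the 4 cued flowers rewarded, out of 2 rewarded flowers
total), making a cued flower `cue_reward_advantage()` = 3 times more
likely to reward than a randomly chosen one.

Per treatment group the pipeline reports the cued-landing count and
proportion, an exact binomial test against 1/3 (two-sided by default,
using the point-probability rule: every outcome whose probability does
not exceed that of the observed count, with a 1e-7 relative tolerance,
contributes to the p-value), and a 90% adjusted-Wald (Agresti–Coull)
interval — the score-centre interval obtained by adding `z^2` pseudo-trials
and `z^2/2` pseudo-successes, clamped to [0, 1]. Ninety percent is the
conventional display level for these group bars and is the package
default.

Treatment effects are estimated by logistic regression with a Gaussian
random intercept per colony, fitted by marginal maximum likelihood with
adaptive Gauss–Hermite quadrature (`lme4::glmer`, 25 quadrature points by
default; the colony effect is a single scalar, for which adaptive
quadrature is accurate and fast). Wald `z = estimate/SE` and two-sided
normal p-values are reported, matching the convention in which such fits
are usually printed. The full model uses cue type, reward distribution
and their interaction; split models (one per cue type) use reward
distribution alone.

**Indicator orientation.** Throughout the models and the generator,
indicators are coded social cue = 1 and high-variance experience = 1,
with the non-social/no-variance cell as the reference at the chance
baseline. Positive coefficients therefore mean *more* cue use for social
cues or after high-variance experience — the direction in which the
headline effect (social cue x high variance) is positive. Reversing the
distribution indicator would flip the signs of the distribution and
interaction terms but change nothing else.

Edge cases are handled by reporting, not by silent repair: a single
colony triggers a warning and a plain-logistic fallback with
`random_intercept_sd = 0`; complete separation is flagged
(`separation_suspected`) while the divergent estimates are still shown,
keeping output comparable to standard mixed-logit summaries.

`first_k_summary()` averages each bee's proportion of cued landings over
its first `k` landings (`k` in {4, 10} by convention); bees with fewer
than `k` landings contribute the proportion over the landings they do
have, rather than being discarded.

## The synthetic generator

`generate_choice_dataset()` emulates only the *statistical structure* of
the test phase: 57 bees (16 social/high-variance, 17 social/no-variance,
12 + 12 non-social — only the non-social total of 24 is fixed by the
design, the even split is a choice), assigned round-robin to 3 colonies;
one Gaussian colony intercept per colony (SD 0.3 on the logit scale — an
assumed, configurable value of a plausible magnitude for between-colony
heterogeneity); a cell-specific success probability built from the
chance baseline `logit(1/3)` plus configured logit effects; and
independent Bernoulli landings within a bee. Default effect sizes
(split parameterization: +3.125 within the social cue, +0.696 within the
non-social cue; full parameterization: -1.138 cue, +0.733 distribution,
+2.593 interaction) are plausible magnitudes for this design used as
recovery targets for testing — not ground truth to be reproduced.

What the generator deliberately does **not** emulate: flower geometry and
spatial position effects, bout timing and the bout cap, learning within
the test bout (landings are exchangeable within a bee), and any
cue-training carry-over beyond the cell means. Passing pipeline tests on
generated data therefore demonstrate statistical correctness of the
estimators under the generating model, not behavioural realism of real
bees — with real data, within-bout learning would make later landings
non-exchangeable, which is why first landings are the primary outcome.

## Scale of the checks

The test suite runs the full default simulation (100 replicates per
regime, 5000 steps each) for the headline contrast; drift neutrality at
200 single-patch replicates of 400 steps; regime-degeneracy equivalence
at 100 replicates of 1200 steps per arm; the concentration sweep (12, 6,
2 rich patches) at 30 replicates each; and generator-model closure at
2000 bees x 200 simulations plus one 40,000-bee recovery fit. Oracle
checks (binomial enumeration for all n up to 25, direct Agresti–Coull
evaluation, a 64-point Gauss–Hermite + direct-optimisation fit of the
mixed logit) are exact-tolerance comparisons on small fixtures.

## Known limitations

The simulation has no spatial structure, travel or handling costs, no
within-step depletion, no memory decay, and no within-lifetime switching
between learning strategies; the evolved proportion is a property of the
strategy dichotomy, not a claim about plastic information use. The
analysis pipeline assumes one random-intercept level (colony) and
binomial outcomes; with only three colonies the random-intercept SD is
itself poorly identified (fixed-effect inference remains well calibrated
in the closure tests, but the variance component should not be
over-interpreted).
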