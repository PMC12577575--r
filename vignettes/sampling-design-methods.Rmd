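---
title: "Methods: simulating multiple-paternity sampling designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating multiple-paternity sampling designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paternitypower)
```

## The question the simulator answers

Parentage studies infer the number of males siring a clutch from a sample
of genotyped offspring. A father whose offspring are absent from the sample
is invisible, so the identified count is a lower bound on the true count.
This package quantifies that gap by Monte Carlo: it simulates clutches (and
whole breeding seasons) under explicit demographic and mating assumptions,
applies the intended sampling design, and reports the proportion of
replicates in which the design found every father — the design's
*confidence*, the operational notion of statistical power used throughout.

Genetic analysis is assumed perfect: every sampled offspring is assigned to
its true father, with no genotyping error, marker limitation, or allele
dropout. All results are therefore about sampling effort alone and are
optimistic with respect to laboratory reality.

## Within-clutch model

A clutch with true father count $X = F \in \{1,\dots,5\}$ is simulated as:

1. Egg count $S \sim \mathrm{round}(N(\mu_{eggs}, \sigma_{eggs}))$,
   redrawn while $S < 1$. Defaults $\mu_{eggs} = 100.58$,
   $\sigma_{eggs} = 22.61$ (eggs; field estimates from a green sea turtle
   rookery). Five is the cap on fathers because field evidence for more
   than five sires per clutch is lacking in this system.
2. Each egg independently receives a father with probabilities given by the
   contribution mode (see `?contribution_weights`). Per-egg assignment
   means a father can sire zero eggs — essential, because it is what keeps
   even whole-clutch censuses below 100% confidence under the skewed
   dominant modes.
3. $\min(n, S)$ offspring are drawn without replacement; the identified
   count $Y$ is the number of distinct fathers observed.

Repeating this `reps` times estimates $P(Y \mid X)$ for one mode and one
sample size; stacking $X = 1..5$ gives the identification matrix. The
`mixed_dominant` meta-mode re-resolves to Dominant 50/70/90 (probability
1/3 each) independently for every clutch, because dominance skew is a
property of a mating event rather than of a population or a female.

**Analytic cross-check.** A uniform without-replacement subsample of
i.i.d.-labeled eggs is itself i.i.d., so at fixed clutch size the
probability of observing all $F$ labels has the inclusion–exclusion closed
form implemented in `analytic_identify_all_probability()`. The test suite
verifies the closed form against brute-force enumeration at tiny sample
sizes, then verifies the simulation against the closed form integrated over
the clutch-size distribution (a truncated-normal quadrature). Two
subtleties this double-check exposed are worth recording: the formula does
*not* apply to a clutch with a fixed father composition (a fixed 90/10
clutch gives a hypergeometric 0.984 where the i.i.d. model gives 0.966),
and integrating over clutch size matters — for Dominant 90 with five
fathers and $n = 96$, 41% of clutches are smaller than 96 eggs and the
confidence is 0.63, not the 0.69 obtained at a fixed 100-egg clutch.

## Posterior on the true father count

Bayes' theorem converts $P(Y \mid X)$ into $P(X \mid Y)$. The prior
$P(X)$ is a free choice: the package defaults to uniform over $\{1..5\}$,
which reproduces the published conditional-probability tables within
Monte-Carlo tolerance (the acceptance tests check all cells at ±0.02), and
accepts any substitute — e.g. `father_count_prior("polyandry_decreasing")`
for the empirical mating-number distribution. Observing $Y = 5$ is handled
by logic, not division: five identified implies five contributed, the
modeled maximum. A $Y$ whose marginal probability is zero (never observed
in the replicates) yields an `NA` row with a warning rather than a silent
`NaN`, so downstream code must confront the undefined case explicitly.

## Within-season model

One season proceeds in four stages:

1. **Pool.** `round(osr * n_pop)` males (ties away from zero; the rounding
   convention is our choice, as is rejecting configurations with zero males
   or zero females). Each male draws a capacity of 1–5 mates from the
   polygyny distribution and contributes that many slots.
2. **Mating.** Females are processed in uniformly random order — the
   ordering policy is not dictated by the model description, and random
   order avoids giving early indices systematically better access to the
   pool. Each female draws a target of 1–5 mates from the polyandry
   distribution and removes slots of distinct males, drawn uniformly over
   slots. A female finding fewer distinct males than her target mates with
   all that remain (partial mating): discarding her entirely would make
   pool exhaustion discontinuous in the parameters. When the pool is empty,
   remaining females do not nest.
3. **Nesting.** Each mated female lays
   $\mathrm{round}(N(\mu_{clutch} = 4.95, \sigma_{clutch} = 2.09))$
   clutches, redrawn to at least one (whether a mated female could lay zero
   clutches is left open by the model description; we forbid it, so
   "mated" and "nested" coincide). Eggs are assigned among her mates with
   the contribution weights; the mate drawn first at mating holds the
   dominant position for all her clutches, since dominance plausibly
   reflects a stable attribute of the pairing rather than a per-clutch
   lottery (mixed-dominant skew, by contrast, is re-drawn per clutch).
4. **Sampling.** `ceiling(fraction * n_clutches)` clutches are drawn
   uniformly from the whole season's clutches and each is subsampled with
   `n_per_clutch` offspring. A replicate succeeds when the identified males
   number at least `ceiling(threshold * breeding_males)`.

The success denominator is the set of males that *mated*, including any
that sired no egg. This matches the quantity a breeding-sex-ratio study
wants (males that bred) and is the stricter reading; it is why full-census
confidence can sit below 1 under Dominant 90.

Identification within sampled clutches is simulated directly egg by egg
rather than via a lookup of the within-clutch probability tables. A lookup
would need a rule for *which* fathers are identified, which the
table alone does not determine; direct simulation needs no such rule and is
the canonical mechanism the tables themselves were estimated from. Our
analysis of the alternative (a uniformly random identity assignment
consistent with the tables) puts the per-father per-clutch miss probability
at 0.36 versus 0.45 for direct simulation in the most skewed scenario —
close, but not identical; direct simulation is the documented choice.

## Numerical and reproducibility choices

* Normal-to-integer conversion rounds ties away from zero (base `round()`
  rounds to even) and redraws values below 1. For egg counts the truncation
  point lies 4.4 SD below the mean and is negligible; for clutch counts it
  lies 2.1 SD below and shifts the realized mean from 4.95 to 5.04 — the
  tests assert the truncated-normal value, not the nominal mean.
* All randomness flows through R's global RNG; `run_*` sweep functions and
  the CLI take a `seed` and seed once per run, making every output table
  exactly reproducible at a fixed seed and replicate count.
* Fraction sweeps (`season_fraction_sweep()`) use common random numbers:
  each replicate simulates one season, one random clutch permutation
  provides nested clutch subsets for all fractions, and each clutch's
  offspring subsample is drawn once. Marginally each fraction's estimate is
  unchanged; jointly the estimated confidence curve is monotone
  non-decreasing by construction, and a 20-point fraction grid costs one
  season per replicate instead of twenty.
* `minimal_clutch_fraction()` returns `NA` when even sampling every clutch
  misses the target confidence. In the worst-case scenario (operational sex
  ratio 0.7, Dominant 90, uniform polyandry, no polygyny, 32 offspring per
  clutch) this is the actual outcome: a father contributing 2.5% of a
  clutch's eggs evades a 32-of-100 subsample 45% of the time, and with
  ~70 breeding males a full census at 32 offspring per clutch identifies
  all of them in only about a third of seasons. The reported "required
  fraction" for that scenario is therefore censored at 100%.
* Default grids: operational sex ratio 0.05–0.95 and clutch fraction
  0.05–1.00, both in steps of 0.05 (the source ranges are stated without a
  step; 0.05 matches the published figures' resolution).

## What the generator does and does not emulate

The simulator reproduces demographic stochasticity (clutch counts, clutch
sizes, mate numbers), mating-pool exhaustion, paternal skew, and sampling
noise. It does **not** model genotyping error or marker resolution,
density-dependent or size-assortative mating, sperm storage across seasons,
interannual variation, or father counts above five. Passing tests
demonstrate internal consistency with the stated model and reproduction of
the published tables under that model — not that any real rookery follows
the model. The mating-number distributions themselves are a strong
assumption: the decreasing variant is derived from observed multiple
paternity rates, but polygyny in sea turtles is essentially unquantified,
which is why all three polygyny settings are first-class.

## Problem sizes

The test suite runs the published scale where it matters for comparison —
10,000 clutches per father count for the identification matrices and
posterior tables, 1,000 seasons per grid point for the two season-scale
scenarios — and smaller replicate counts (a few hundred to a few thousand)
for structural and invariant checks, with Monte-Carlo tolerances set to
four standard errors of the estimate under test. The full published
response surfaces (19 sex ratios × 20 fractions × 6 modes × 6 mating
systems × 10,000 replicates) are reproducible with `run_season_grid()` but
are deliberately not part of the default test run.
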