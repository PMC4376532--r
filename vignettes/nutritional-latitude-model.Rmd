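---
title: "The nutritional-latitude model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nutritional-latitude model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutlat)
library(dplyr)
```

## The model

`nutlat` simulates the evolution of *nutritional latitude* — a heritable
tolerance of nutritional imbalance — in a population of foragers that
compete over limited feeding opportunities. The model combines three
ingredients.

**The Geometric Framework.** The environment is a two-dimensional
nutrient space (protein on x, carbohydrate on y). An individual's
position is its nutritional state; all individuals share an intake
target IT = (500, 500), the ideal amount and blend of the two
nutrients. Each food is a rail from the origin with slope equal to its
carbohydrate:protein ratio V; eating moves the state parallel to the
rail of the food being consumed, by at most φ = 2 nutrient units per
iteration. Appetite follows the *nearest-distance rule of compromise*:
on a rail with angle α_f, an individual would eat

  A = ‖V_T‖ · cos β,   β = |α_ideal − α_f|,

the scalar projection of the vector V_T from its state to the IT onto
the rail — i.e. the distance to the rail's closest approach to the IT
(the *point of nutritional compromise*). Fitness decays exponentially
with the normalised distance to the target,

  F = exp(−μ · D_N),   μ = 2,

where D_N is the Euclidean distance divided by the origin-to-target
distance 500√2, so every individual starts at F = e^−2 ≈ 0.135 and
F = 1 exactly at the IT.

**Contest competition.** Food abundance a limits each rail to
capacity = a·N_ind/N_food simultaneous feeders; competition intensity
is summarised as c = 1 − a/N_food, one minus the proportion of the
population each rail can support. The capacity is used as a real
number: a food is at capacity as soon as its occupancy reaches it.
A searcher arriving at a full rail must displace a randomly chosen
occupant through a dominance contest it wins with probability

  Q_ij = 1 / (1 + exp(−η (F_i − F_j))),

a logistic function of the fitness difference with steepness η = 25 by
default (10 and 20 model noisier hierarchies). Because well-fed
individuals win contests, keep good foods, and get better fed, a
winner effect can emerge.

**Nutritional latitude and the leave rule.** Each individual carries a
heritable trait K ∈ [0, 1]. While feeding it may spontaneously abandon
its rail with probability

  P_leave = (1 − K) · |α_ideal − α_f| / (π/2) + max{0, (K·φ − A)/φ},

clamped to [0, 1]. Low-K individuals (nutritional specialists) abandon
imbalanced rails quickly and keep searching for a balanced one; K = 1
individuals (generalists) exploit any rail until the appetite left on
it falls below φ — in particular they leave with certainty only at the
point of compromise.

## Scheduling

Each generation consists of 500 iterations (an alternative 354 is
configurable) of four phases, each completed by the whole population
before the next begins:

1. **Choose Food** — individuals not on a rail pick one uniformly at
   random, in a fresh random order with immediate updates; if the rail
   is at capacity they challenge a random occupant. The loser — failed
   challenger or displaced occupant — is displaced for the rest of the
   iteration and its displacement count increments.
2. **Eat** — every feeding individual records β at its current state
   and moves min(A, φ) along its rail.
3. **Calculate Fitness** — all fitnesses are recomputed.
4. **Leave** — displaced individuals resume searching; feeding
   individuals leave with probability P_leave evaluated at the
   post-move state. A leaver re-chooses a food (possibly the same one)
   at the next iteration's choose phase.

Negative appetites (a rail leading away from the target, e.g. past the
compromise point) are clamped to zero — intake is physically
non-negative — and the leave rule then drives departure. A state
exactly at the target has appetite zero and β defined as zero. The
per-individual β statistic reported by `run_generation()` is the sum
of β over feed events divided by the number of *iterations*, so
iterations spent displaced from food contribute zero; this is the
convention under which the model's published group means reproduce,
and the feed-event count is reported alongside so a per-feed-event
mean remains computable.

## Evolution

Offspring always number N_ind = 150, start at the origin and inherit K
from a parent, plus Gaussian mutation (SD 0.025) clamped to [0, 1].
Under **general selection** only individuals with final fitness
strictly above 0.5 may breed, and parents are sampled
fitness-proportionately among them; if nobody crosses the threshold
the population is extinct and the run stops with a flag. Under
**truncated selection** the generation has no fixed length: the first
10% of the population to exceed the cutoff (0.5 or 0.9) become equally
weighted parents, so extinction cannot occur. When several individuals
cross in the same iteration and push the arrival list past the target,
the pooled list is randomly subsampled to exactly the target size. We
weight truncated-regime parents uniformly because arrival order, not
relative fitness, is the selective filter in this regime; a
fitness-weighted variant can be emulated through the general mechanism
with a high cutoff. A safety cap (50 × the nominal 500 iterations)
aborts a truncated generation that can never reach its cutoff — e.g. a
cutoff of 0.9 in an environment whose best attainable state is farther
from the target — with a diagnostic error.

The founder population has K = 1 throughout. Because mutation is a
clamped random walk, K is conserved exactly when the mutation SD is
zero, and under neutrality (no fitness variation) the stationary
distribution of K is approximately uniform away from the boundaries —
both properties are exercised in the test suite.

## Random streams and the two engines

The per-iteration scheduler exists twice: a compiled engine (Rcpp) and
a naive per-agent R reference. Both consume R's uniform stream through
the same primitives — bounded integer draws `floor(u·n)` and
Fisher–Yates permutations — so for any seed their trajectories are
identical; the suite verifies this bit-for-bit on small instances at
every prefix length. Random draws occur where order matters: one
permutation of the searchers per choose phase, one uniform per contest
and per food choice, and one uniform per feeding individual (in index
order) in the leave phase. The eat and fitness phases involve no
interaction between individuals, so no permutation is consumed there.
Replicate orchestration derives one recorded seed per replicate from a
master seed, making every batch exactly reproducible.

## Environments and presets

The published figure panels draw food values from the pool
{0.0625, 0.5, 1, 2, 16} without tabulating each panel's combination;
the package therefore ships named presets that are documented
interpretations and can be overridden by explicit V vectors:

| preset | V | description |
|---|---|---|
| `3-food-mild` | 0.5, 1, 2 | balanced food plus two mildly imbalanced complementary foods |
| `3-food-extreme` | 0.0625, 1, 16 | balanced plus two severely imbalanced complementary foods |
| `2-food-mild` | 1, 2 | balanced plus one mildly imbalanced food |
| `2-food-severe` | 1, 16 | balanced plus one severely imbalanced food |
| `2-food-complementary-mild` | 0.5, 2 | two imbalanced complementary foods |
| `2-food-complementary-extreme` | 0.0625, 16 | two severely imbalanced complementary foods |

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| IT | (500, 500) | nutrient units | fitness optimum; with φ = 2 a direct route needs ≈ 354 iterations |
| φ | 2 | nutrient units / iteration | maximum intake per feeding event |
| μ | 2 | — | steepness of the fitness decay with distance |
| η | 25 | — | power of the fitness gap to decide contests |
| N_ind | 150 | individuals | population size, constant across generations |
| c | 0–0.95 | — | competition intensity (sets abundance and capacity) |
| iterations/generation | 500 | — | feeding opportunities per reproductive period |
| generations | 1000 | — | long enough for K to equilibrate in the published setting |
| mutation SD | 0.025 | K units | scale of heritable variation introduced per generation |
| cutoff | 0.5 | fitness | breeding condition threshold (0.9 variant for truncated runs) |

## What the simulations show

A compact summary of behaviour the test suite and acceptance script
actually recompute:

- In the 3-food mild environment with 75 individuals at K = 0.25 and
  75 at K = 0.85, low-K individuals maintain a smaller mean β but
  accumulate more displaced iterations than high-K individuals, at
  both c = 0.683 and c = 0.767, and the displacement gap widens with
  competition.
- The relative fitness of the high-K strategy is negative at every
  frequency at c = 0.683, positive at every frequency at c = 0.767,
  and crosses zero at an intermediate frequency at c = 0.725 —
  positive frequency dependence around the strategy transition.
- Evolving populations settle at low K (with wide percentile spread)
  under weak competition (c = 0.3), and in the 2-food severe
  environment at c = 0.625 are driven toward very low K (≈ 0.06 in
  the published reading; our replicate means fall below 0.15). In the
  3-food mild environment, evolutionary replicates at c = 0.7 remain
  in the low-K regime in this implementation, so the high-latitude
  equilibrium appears only at higher competition — consistent with
  the frequency-dependence structure above, in which the tolerant
  strategy cannot invade below c ≈ 0.725 and is unconditionally
  favoured at 0.767, but not with the published equilibrium-figure
  reading that places the transition at c = 0.7. The same runs match
  the published behavioural statistics to ~1%, so we regard the
  transition point as an emergent, highly sensitive threshold on
  which the published account is itself internally in tension.
- At sufficiently high competition no individual reaches breeding
  condition under general selection and the population goes extinct;
  under truncated selection runs always complete.

## Numerical and design choices

- **Angles** are measured counter-clockwise from the protein axis, in
  radians internally; β statistics are reported in degrees. β is taken
  as `|α_ideal − α_f|` without wrapping; for states within the scope
  of the dynamics both angles lie in [0, π].
- **Capacity comparisons** use the real-valued capacity directly
  (occupancy ≥ capacity means full), avoiding an arbitrary rounding
  rule and preserving the interpretation of c as a supportable
  population proportion.
- **Quantiles** of K (2.5th/97.5th percentiles) use the
  linear-interpolation convention (R type 7), recorded in every output
  manifest.
- **Displaced opponents lose the whole iteration**, exactly like
  failed challengers, and re-choose the next iteration with no memory
  of (or exclusion from) their previous food.
- **Degenerate states**: an individual exactly at the target has
  appetite 0 and β = 0; zero-length generations return the initial
  state with fitness e^−2 and no statistics.
- **Problem sizes in the tests**: the acceptance-level checks run the
  behavioural experiments at the full published size (150 individuals,
  500 iterations, 30 replicates) and the evolutionary equilibria at 5
  replicates of several hundred generations — the trajectories
  equilibrate well within that horizon at the competition levels
  checked — with the full 30 × 1000 configuration available through
  `run_competition_sweep()`.

## What the generator does and does not emulate

Simulated data reproduce the model's own idealisations: a single sex,
a shared and fixed intake target, inexhaustible rails (only slots are
limited), no spatial structure, no movement or search costs beyond
lost feeding opportunities, symmetric fitness costs of nutrient excess
and deficit, and the nearest-distance rule of compromise. Passing
tests therefore validate the implementation of this idealised model —
not the behaviour of real foragers, for which intake targets vary
among individuals and sexes, fitness landscapes can be asymmetric, and
alternative rules of compromise (e.g. equal-distance) are documented.

## Known limitations

- Rules of compromise other than nearest-distance are out of scope.
- The nutrient space is strictly two-dimensional.
- Food values per published figure panel are interpretations (see the
  preset table); explicit V vectors reproduce any other combination.
- Sweeps are executed serially; at the published scale (30 replicates
  × 1000 generations per grid point) a full grid is an overnight job
  on one core.
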