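---
title: "Multiobjective spider-wasp optimization: model, parameters and design choices"
author: "moswo package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective spider-wasp optimization: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moswo)
```

## The optimizer

`moswo()` approximates the Pareto front of a box-constrained multiobjective
minimization problem with a population of candidate solutions ("spider
wasps") that evolve through five behavior families borrowed from the
spider-wasp foraging cycle:

* **searching** (exploration): either a differential step
  `x + mu1 (x_a - x_b)` between two random population members, with
  `mu1 = rn * r1`, `rn ~ N(0, 1)`, `r1 ~ U(0, 1)`, or a bounded random jump
  `x + mu2 (L + r2 (H - L))` with `mu2 = cos(2 pi l) / (1 + e^l)`,
  `l ~ U(-2, -1)`;
* **following** (chase): `x + C * 2 r5 (x* - x)` toward an archive leader
  `x*`, with a per-dimension `r5 ~ U(0, 1)` and a speed factor
  `C = C0 (1 - t / t_max)` that decays linearly over the run;
* **escaping**: a multiplicative contraction `x * vc`,
  `vc ~ U(k_low, k_high)` per dimension — the randomized restart of the
  family;
* **nesting** (exploitation): `x* + cos(2 pi l)(x* - x)`, a move along the
  line through the current position and the leader;
* **mating**: uniform crossover, each coordinate taken from a partner with
  probability `CR`.

Selection is elitist at two levels.  An external archive keeps the best
mutually non-dominated solutions seen so far and is truncated to its
capacity by removing the lowest crowding-distance member one at a time.
The population itself undergoes (mu+lambda) environmental selection every
generation: parents and offspring are pooled, ranked by non-dominated
sorting, and the best `N` survive by (rank, crowding) order.  `N` follows a
linear reduction schedule from `pop_size` down to `pop_min`, which shifts
the evaluation budget from broad early search to concentrated late
refinement.  Constraints are handled by constraint dominance: a feasible
solution beats any infeasible one, infeasible solutions compare by their
violation, and objective dominance applies only among feasible ones.

### Behavior wiring

The source method leaves the control flow between the behavior families
open (its two pseudocode variants disagree: one branches stochastically per
individual, the other applies all phases in sequence), so the engine's
wiring is a design choice of this package.  Each individual each
generation:

1. mates with probability `TR` (partner drawn from the archive half the
   time, otherwise from the population);
2. otherwise searches with probability `1 - t / t_max` (the exploration
   share decays linearly to zero);
3. otherwise hunts an archive leader chosen by a binary crowding-distance
   tournament: with probability 0.75 it chases — following the leader, or
   escaping when a coin (`r2 > r3`) or the distance threshold
   `0.5 ||H - L|| (1 - t/t_max)` says the prey is out of range — and with
   probability 0.25 it performs the nesting move.

Two refinements matter on separable multimodal landscapes (the
Rastrigin-type distance function of ZDT4 is the canonical case):

* search, follow and nest proposals are recombined with the parent
  through the mating operator (always transferring at least one
  coordinate), so variation can advance one coordinate at a time;
* the escape contraction is applied to a *single* coordinate, chosen with
  probability proportional to its magnitude (the contraction is
  multiplicative, so that is where it has leverage).

Without the first, a proposal that changes many coordinates at once is
almost always rejected by selection even when one coordinate crossed a
fitness barrier successfully, and — worse — on concave fronts a run whose
first archive member is the exact corner point funnels every coordinate
toward that corner and collapses; per-dimension gating lets the distance
coordinates converge while the position coordinates keep their diversity.
Without the second, multimodal repair stalls because a contraction across
all coordinates only survives if every coordinate lands well.

With per-individual greedy replacement instead of pooled environmental
selection the optimizer collapses on concave fronts: the corner point
`(0, 1)` of a concave bi-objective front dominates every candidate whose
distance function has not yet converged, the archive then holds a single
leader, and every exploitation move pulls the population into that corner.
Pooling parents and offspring and truncating by (rank, crowding) — the
same rule the reduction schedule uses — preserves spread along the front
while the distance function converges, and is therefore used throughout.

### Iteration horizon

The budget is counted in objective evaluations.  With population reduction
enabled, a generation costs between `pop_size` and `pop_min` evaluations,
so the engine sets the schedule horizon to
`t_max = 2 * budget / (pop_size + pop_min)`; all linear schedules (speed
factor, exploration share, escape threshold, population size) then reach
their endpoints as the last evaluations are spent.  Without reduction,
`t_max = budget / pop_size`.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 100 | initial population (the benchmark protocol value) |
| `pop_min` | 20 | final population of the reduction schedule |
| `budget` | 10,000 | objective evaluations |
| `archive_size` | 100 | external archive capacity |
| `TR` | 0.3 | mating probability per individual per generation |
| `CR` | 0.3 | crossover rate of the mating operator and the per-dimension proposal gates |
| `C0` | 2 | initial speed factor of the following move |
| `escape_scale` | 0.5 | scale of the distance threshold for escaping |
| `k_vc_low`, `k_vc_high` | -1, 1 | support of the escape contraction factor |

`pop_size`, `C0`, `TR` and the benchmark budgets follow the source method's
stated protocol; `CR`, `pop_min` and the chase/nest split are not specified
there and were fixed once from benchmark behavior across the ZDT/DTLZ
families (CR around 0.3 keeps coordinate-wise transfer effective on
multimodal problems without slowing convergence elsewhere; reducing to a
fifth of the population funds a long exploitation phase, and with
per-dimension gated variation the smaller final population retains enough
diversity for multimodal repair).  The archive capacity — also never
stated — defaults to the population size, 100.

## Benchmarks and indicators

ZDT1-4, ZDT6 and DTLZ1-7 are implemented in their canonical formulations
(dimensions 30 for ZDT1-3, 10 for ZDT4/6; three objectives and
`D = M - 1 + k` with k = 5, 10 or 20 for the DTLZ family), each with an
analytic Pareto-front sampler that spreads points uniformly in the front's
natural parameterization.  The disconnected fronts (ZDT3, DTLZ7) are
sampled through a non-domination filter; for DTLZ7 the filter exploits the
separability of `f3 = 6 - q(f1) - q(f2)`, `q(t) = t(1 + sin 3 pi t)`, so
the front is the product of two per-coordinate staircase sets.

Quality indicators:

* **IGD** — mean distance from a dense front sample (1,000 points for two
  objectives, 5,000 for three) to the nearest archive point, on the raw
  objective scale;
* **hypervolume** — exact (sweep in 2-D, slicing in 3-D) after normalizing
  objectives by the analytic front's ideal and nadir points, with the
  reference point at 1.1 per objective.  This convention reproduces the
  closed-form value 0.8767 for the dense ZDT1 front, matching the magnitude
  of the published table entries;
* **spread (Delta)** — extreme-point gaps plus the mean absolute deviation
  of consecutive (2-D) or nearest-neighbour (3-D) gaps, normalized; 0 is a
  perfectly uniform front that reaches the extremes.

Degenerate cases are fixed by convention: a front of one or two points has
infinite crowding everywhere; an objective with zero range contributes
nothing to crowding; spread is undefined (infinite, with a warning) below
three points; hypervolume counts only points that strictly dominate the
reference point.  Ties in the per-objective crowding sorts are broken by
the original index, which keeps every quantity deterministic under a fixed
seed.

The benchmark campaign (`run_campaign()`) runs 25 independent seeded runs
per problem — seeds `base_seed + 1 ... + 25` — at 10,000 evaluations for
ZDT and 20,000 for DTLZ, and reports per-run and mean/sd indicator tables.
A campaign given an output directory writes one archive file per run
atomically and resumes from completed files if interrupted.

## The drug-regimen layer

The regimen design problem optimizes a four-slot decision vector — dose of
drug A (mg per administration), dosing interval (h), dose of co-drug B
(mg), treatment duration (weeks) — against three objectives derived from a
pharmacokinetic/pharmacodynamic cohort table with the columns patient ID,
the two doses, Cmax, Tmax, AUC, therapeutic effect (%), toxicity grade
(1-3) and therapeutic index.

Three models are fitted to the cohort once: a linear exposure model
`AUC ~ doseA + doseB`, an Emax (Hill) response model of effect versus AUC,
and an ordinal toxicity model of grade versus AUC (proportional-odds
regression, falling back to empirical mid-gap thresholds with logistic
smoothing when the grades are perfectly separated in AUC — the usual case
for threshold-generated data).  A regimen's steady-state exposure is its
predicted per-dose AUC scaled by dosing frequency relative to a reference
interval (12 h); its predicted effect is additionally attenuated by a
saturating duration factor `duration / (duration + 2)` so that very short
courses cannot score full efficacy.

The three scores are linear penalties on the model predictions —
efficacy `E = E_max - w1 * AE` with `AE` the predicted response shortfall
(100 minus predicted effect), safety `S = S_max - w2 * AR` with `AR` the
expected toxicity grade, and cost `C = C_max - w3 * Cost` with the raw
course cost from per-mg drug prices, the number of administrations
`duration * 7 * 24 / interval` and a weekly care cost.  Although the
problem statement writes "minimize (E, S, C)", E and S are quantities one
wants large; the only internally consistent reading — and the one
implemented — minimizes the deductions `(w1 AE, w2 AR, w3 Cost)`, and
`regimen_report()` prints both conventions.  The `AE`/`AR`/`Cost`
predictors themselves are not specified by the source method; the fitted
cohort models above are this package's explicit stand-ins, built only from
the published table schema.  Because Pareto optimization is
scale-invariant per objective, the `w1-w3` weights are redundant unless
used asymmetrically; they default to 1 and are kept for the score
convention.  A predicted-Cmax ceiling (default 300 ng/mL) enters as an
inequality constraint through constraint dominance.  The therapeutic index
is reported as the ratio of the toxic exposure (where the expected grade
crosses 2.5) to the half-maximal effective exposure; it is a report
column, not an objective.  The same four-slot vector serves
chemotherapy-style encodings (dose, infusion rate, rest period, cycles) by
renaming the bounds; no separate chemotherapy response model is provided.

### The synthetic cohort generator

`generate_cohort()` emulates a two-drug antiviral dose-ranging table:
doses on a grid (drug A 100/150/200 mg, drug B 50-150 mg in 25 mg steps),
per-dose AUC linear in the doses (`770 + 3.75 doseA + 1.5 doseB` ng·h/mL)
with 7% lognormal inter-patient variability, Cmax proportional to AUC
(ratio 0.135), Tmax uniform on 1.5-2.5 h, effect from an Emax model
(Emax 100%, EC50 550 ng·h/mL, Hill 2, additive noise sd 2.5%) clipped to
[0, 100], toxicity grade by thresholding the realized AUC at 1375 and
1500 ng·h/mL, and therapeutic index `AUC / grade` — the exposure margin
per toxicity grade, which reproduces the reference table's TI column
exactly (for grade-1 patients it coincides with AUC).  These constants
were calibrated once against the published sample table and are not meant
to be tuned per run.

What the generator does *not* emulate: real PK/PD data have
multi-compartment kinetics, covariate effects (weight, renal function),
censored or missing cells, dose-interval variation within the table, and
toxicity that depends on Cmax as well as AUC.  Passing tests on generated
cohorts therefore demonstrate that the fitting + optimization pipeline
recovers a known generative structure, not that any produced regimen is
clinically valid.

## Problem sizes used by the test suite

The package's own checks run the full published protocol where it is cheap
(25 runs of 10,000/20,000 evaluations complete in well under two minutes
per problem on one core) and smaller instances elsewhere: unit tests use
budgets of 500-5,000 evaluations and populations of 25-80, the dominance
and archive oracles check 1,000 random populations of up to 100
individuals against exhaustive pairwise brute force, hypervolume is
cross-checked against 10^5-sample Monte-Carlo estimates, and the regimen
recovery test compares a 3,000-5,000-evaluation run against a
~40,000-point grid-search oracle.

## Known limitations

* On ZDT4 the optimizer reaches a mean IGD about 1.5-2x the published
  value at the stated budget: full convergence of a 9-variable Rastrigin
  distance function in 10,000 evaluations depends on coordinate-repair
  luck, and occasional runs finish with one coordinate a basin away.
* DTLZ1 and DTLZ3 (Rastrigin distance functions with 3 objectives) are
  implemented and tested for correctness but generally do not converge at
  20,000 evaluations — consistent with the published tables, which report
  the same failure for the source method itself.
* Exact hypervolume is limited to two and three objectives; the spread
  metric beyond two objectives uses the nearest-neighbour generalization.
* The engine is serial; objective functions are assumed cheap and
  vectorizable.
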