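---
title: "The dispersyn model: learning, exploration and dispersal under developmental plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dispersyn model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dispersyn` simulates a metapopulation of `n_patches` habitat patches
connected by random global dispersal: a dispersing individual is equally
likely to end up in any patch, its natal one included. Generations are
discrete and non-overlapping; individuals are haploid and reproduce
asexually at the end of their one-season life. Fitness is income-based:
it is the value of resources gathered during the season, discounted by
the cost of the expressed learning ability.

Every individual carries five loci on [0, 1]: a dispersal tendency `D`
and two pairs of phenotype-specific loci, `(L_R, E_R)` for the resident
phenotype and `(L_D, E_D)` for the disperser phenotype. Development is a
single irreversible switch at birth: the individual becomes a disperser
iff `D` exceeds one fresh uniform draw, and from then on expresses only
the matching learning/exploration pair. The unexpressed pair is carried
silently and passed on — this is what lets the two phenotypes' traits
evolve independently from a shared genome, and what makes
mutation–selection balance visible: a locus that is rarely expressed
feels little selection and drifts toward the neutral mean 0.5 under the
symmetric mutation kernel.

### The foraging economy

Each foraging phase (length `T` = `t_before` or `t_after`) is evaluated
in one closed-form pass per patch and resource type, not by per-time-step
agent stepping — the five stages below are defined as whole-phase
aggregates, and batching them keeps a 300-generation run of 1,200
individuals in the low seconds.

1. **Encounters** `N = A · T · (1 + E)`. Individuals forage in at least
   every second time step; exploration `E` fills in the optional steps,
   so an `E = 0` individual encounters exactly half of what an `E = 1`
   individual does.
2. **Detection** `N' = N · (1 − (1 − C) · E)`. Fast movement costs
   thoroughness; with detectability `C = 1` or `E = 0` nothing is lost.
3. **Learning-discounted handling.** The j-th item of a resource type
   ever handled by an individual yields the value fraction
   `max(0, 1 − (H − 1)/(j · L))`. The phase's handled amount is the sum
   of that term over the `round(N')` items of the phase, with `j`
   continuing from the individual's lifetime ledger for that resource
   type. Experience therefore carries over dispersal if and only if the
   settlement patch offers the same resource type.
4. **Patch cap** `Rmax = T · A · N_individuals / Φ`, with the *fixed*
   carrying capacity, not current occupancy: the cap describes the
   patch's productivity, which does not grow because immigrants crowded
   in.
5. **Competition.** If the patch's summed handled amount exceeds `Rmax`,
   every occupant's amount is scaled by `Rmax / Σ` — the resource is
   fully depleted and shares shrink proportionally.

Fecundity is `F = max(0, V_total · (1 − L · α))`; recruitment draws
exactly `N_individuals` offspring per non-empty patch with probabilities
proportional to `F`; each offspring locus mutates independently with
probability `μ`, by a Gaussian step of SD `mutation_sd` clamped to
[0, 1]. Every `extinction_every` generations, `extinction_count` random
patches are erased after recruitment; an empty patch can only be
recolonised by later immigrants.

## Parameters that matter

| Parameter | Meaning | Reference value |
|---|---|---|
| `n_patches` × `n_individuals` | world size (patches × carrying capacity) | 12 × 100 |
| `t_before`, `t_after` | phase lengths; season `S` is their sum | varied |
| `M` (`dispersal_mortality`) | probability a dispersal attempt is fatal | 0.01 |
| `α` (`learning_cost`) | fecundity discount per unit of expressed `L` | 1.4 |
| `Φ` (`competition_factor`) | divides the patch resource cap | 2 (season sweep), 6 (timing sweep) |
| `μ`, `mutation_sd` | per-locus mutation probability and step SD | 0.1, 0.1 |
| `H` | handling time of the hard resources | 300 (season sweep), 150 (timing sweep) |
| `EX_freq`, `EX_N` | extinction period and patches erased | every 2 generations, 1 patch |

The two shipped presets (`season_preset()`, `timing_preset()`) encode the
reference environments: an easy resource (`V = 1, H = 1, C = 0.5, A = 1`)
present in both patch types, plus one hard, valuable resource
(`V = 10, C = 0.5, A = 5`) per patch type, with the two patch types
equally frequent.

## When can learning pay? (parameter guidance)

Two closed-form bounds shape the dynamics and are worth knowing before
choosing parameters.

*Reachability.* The handling term is positive only for practice counts
`j > (H − 1)/L`. An individual's lifetime practice with one resource is
at most `A · T · (1 + E)(1 − (1 − C)E)` per phase — with `C = 0.5` at
most `1.125 · A · T`, i.e. about `11 T` per phase at `A = 5`. A hard
resource with `H = 300` therefore yields nothing at all unless lifetime
practice exceeds `299 / L`.

*Profitability.* Because the learning cost is multiplicative on total
income, `F = V_total(1 − αL)`, any `L ≥ 1/α` (≈ 0.714 at `α = 1.4`)
zeroes fecundity outright, so a viable learner has `L < 1/α` and its
practice threshold is at least `(H − 1) · α` — concretely `j > 419` at
`H = 300`, `α = 1.4`. With phase lengths `T ≤ 50` (season lengths
`S ≤ 100`) lifetime practice tops out near 560 items and the hard
resource's net payoff remains below the easy-resource baseline, so
selection removes learning investment wherever the locus is expressed.

In that regime the model's dynamics are scale-invariant in `T` (income
scales linearly and fitness-proportional recruitment is invariant to
income scale), and the observed contrast between the two learning loci is
driven by *expression frequency*: at the reference parameters the
population equilibrates at high dispersal tendency (`mean D ≈ 0.85`,
sustained by recolonisation of periodically erased patches against the
small mortality `M = 0.01`), so the disperser-learning locus is expressed
in the majority and selected near zero, while the resident-learning locus
is expressed rarely, feels weak selection, and is pushed upward by
mutation pressure toward 0.5. The desk-scale sweeps in this package
(`S ≤ 100`) accordingly show a uniform `L_R > L_D` contrast and flat
timing cells rather than a crossover; exploring a crossover would require
season lengths long enough for lifetime practice to clear the
profitability threshold (several hundred time steps under the reference
resource settings).

## Numerical and design choices

* **Rounding of `N'`:** half away from zero (`floor(x + 0.5)`). Inputs
  are rarely exactly half-integral; the choice is documented rather than
  consequential.
* **`L = 0` with `H > 1`:** the handling term is defined as 0 (its limit
  as `L → 0+`), avoiding a 0/0.
* **Experience currency:** the lifetime ledger advances by the *rounded
  detected count* (items practiced), not by post-competition amounts —
  competition removes reward, not practice. The alternative (crediting
  only rewarded items) would couple learning speed to patch crowding.
* **Closed-form handling sum:** the per-item sum is evaluated with
  harmonic numbers via `digamma`, and is property-tested against the
  literal per-item loop to below 1e−9 over 10⁴ random tuples.
* **Fecundity floor at 0:** `F` is a sampling weight; negative weights
  are meaningless. An occupied patch whose occupants all have `F = 0`
  recruits uniformly rather than going spuriously extinct.
* **Mutation at the boundaries:** clamping (not resampling) preserves the
  symmetric stationary distribution around 0.5 that the neutral-drift
  diagnostics rely on, at the cost of point masses at 0 and 1.
* **Dispersal destinations include the natal patch** (uniform over all
  patches); with 12 patches the self-return probability is 1/12.
* **A dead disperser is removed entirely** — no post-phase foraging and
  no reproduction; income gathered before the fatal attempt dies with it.
* **Census timing:** records are taken after both foraging phases and
  dispersal but before recruitment, so the expressed-phenotype means
  describe exactly the cohort whose fitness differences drive that
  generation's selection.
* **Founders:** all five loci uniform on [0, 1] (the equilibrium is
  insensitive to the start; trait means settle well within the configured
  run lengths). Patch types are assigned in blocks (first half type 1);
  with global dispersal the spatial arrangement is irrelevant.
* **Seeding:** one R RNG stream per run, seeded once; replicate `k`
  derives seed `base_seed + k − 1`, and sweep cell `i` offsets the base
  by `1000·(i − 1)`. Identical `(config, seed)` reproduces every output
  byte.
* **Equilibrium window:** trailing 10% of recorded generations (minimum
  10). A fixed trailing window is reproducible, unlike visual judgment
  of equilibrium.
* **Sweep comparisons** use population-wide locus means (every individual
  carries both learning loci), since mutation–selection-balance reasoning
  concerns the locus including its silent carriers; expressed-phenotype
  means are emitted alongside as diagnostics.

## What the simulator does and does not emulate

The model is an idealisation aimed at the time-budget logic of learning
and dispersal: global dispersal (no distance or kernel structure), fixed
carrying capacity, a single annual lifecycle, no predation, no sexual
reproduction or diploidy, no condition-dependent dispersal decisions, and
resource economics collapsed to whole-phase aggregates. Passing tests
therefore demonstrate the internal consistency of this economy and its
selection response — not quantitative predictions for any real taxon.

## Problem sizes used

The shipped diagnostics and experiments run at: 12 patches × 100
individuals; 300-generation runs for the season-length sweep over
`S ∈ {20, 30, 50, 100}` with 10 replicates per cell; 500-generation runs
for the timing sweep (`(2,18), (10,10), (18,2)`) and for the
neutral-drift check (10 replicates, selection disabled, final 100
generations averaged). Property tests use 10⁴ random tuples for the
handling-sum oracle and 10⁵ draws for frequency checks.

## Known limitations

* The desk-scale sweeps sit entirely in the learning-infeasible regime
  discussed above; season lengths of several hundred steps (at matching
  computational cost) are needed before the hard resources can repay
  learning investment.
* With `μ = 0.1` and step SD 0.1, mutation pressure is strong; weakly
  selected loci hover near 0.5 with wide per-replicate excursions
  (SD ≈ 0.1 of the 100-generation mean), so neutral-drift diagnostics
  need replicate averaging.
* Under uniform fitness the dispersal-tendency locus is still not
  neutral: colonists of freshly erased patches found the next local
  generation regardless of fitness weighting, which sustains elevated
  `D`. Neutrality diagnostics should read the unexpressed-effect loci.
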