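---
title: "Muller's ratchet with lateral gene transfer: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muller's ratchet with lateral gene transfer: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtratchet)
```

## The model

`lgtratchet` simulates a Fisher–Wright population of `N` haploid
individuals with discrete, non-overlapping generations. An individual is a
vector of non-negative integers `z = (z_1, …, z_g)`: the number of
deleterious mutations carried at each of `g` loci arranged on a circular
chromosome. Runs start from a population entirely free of mutation.

Each generation applies, in order:

* **fitness-proportional reproduction** — `N` offspring sampled with
  replacement from the current generation;
* **mutation** — each offspring draws `n ~ Poisson(U)` new mutations,
  `U = μ·g`, each landing on a uniformly chosen locus (a locus can be hit
  repeatedly; there is no back-mutation);
* **segmental lateral gene transfer (LGT)** — the dying parent
  generation's genomes form the environmental DNA (eDNA) pool, stable for
  exactly one generation. Each offspring independently undergoes at most
  one LGT event with probability `λ` (a Bernoulli draw, not a Poisson
  number of events). An event copies `L` contiguous loci, starting at a
  uniform position and wrapping circularly, from a uniformly drawn donor
  genome onto the same coordinates of the recipient — homologous
  replacement, no translocation. The recipient's load can rise or fall.

Statistics are recorded **after the recombination step**. This is the one
point in the cycle where a positive per-locus minimum
`min_j z_i(j) ≥ 1` is provably irreversible: all subsequent genomes
descend from the current ones (directly or through the eDNA pool), and
mutation only adds. The per-generation record holds the size of the
least-loaded class (LLC; all-zero genomes), the mean load, and the total
fixed mutation levels. `Text` is the generation of the first fixation
anywhere in the genome — the irreversible extinction of the mutation-free
class — and the genome-wide fixation rate `Δm/Δt` is the total fixed
levels at the end of a run divided by its duration.

### Event ordering

Descriptions of this life cycle differ in where the generation boundary is
drawn: one convention applies selection first and lets the newborn cohort
mutate and recombine (selection → mutation → LGT, donors being the parent
generation's final genomes); the other lets the newborn cohort recombine
and mutate before reproducing (LGT → mutation → selection). The package
implements both; `event_order = "methods"` (the first) is the default, and
`"figure1"` (the second) is available as a sensitivity check. In both
orders the statistics point is directly after recombination, so fixation
permanence holds; in the `"figure1"` order that point precedes the
cohort's own mutation step. The two orders give statistically
indistinguishable dynamics at the parameter ranges explored here.

### Fitness

Two functional forms are provided, selected in `fitness_model()`:

* `"linear"` (default): `w = max(0, 1 − Σ_i s_i z_i)`, the classic
  no-epistasis load formula `w_m = 1 − s·m` when `s` is uniform. The
  clamp at zero matters only for loads near `1/s`; a generation whose
  fitness is identically zero is reported as an extinct replicate rather
  than an error.
* `"multiplicative"`: `w = Π_i (1 − s_i)^{z_i}`, every mutation
  independently multiplying fitness by `(1 − s_i)`.

For the selection coefficients this model is about (`s ≤ 0.005`,
`s·m ≪ 1`) the two agree to first order, and every comparative result in
the test suite holds under either. A third conceivable reading,
`w = Π_i (1 − s_i m_i)`, differs from the linear form only at second
order in `s·m` and is not separately implemented.

Selection is either uniform or split into a **core genome** of `g_core`
loci under strong selection (`s_core`, default 0.005) and an **accessory
genome** under weak selection (`s_accessory`, default 0.001). Which loci
are core is itself random: a uniform draw of `g_core` indices without
replacement, made once per replicate from that replicate's RNG stream
(`realize_core_mask()`), so replicate batches marginalise over placements.

## Parameters

| Parameter | Meaning | Units / range | Typical values |
|---|---|---|---|
| `N` | population size | individuals | 100–10,000 |
| `g` | genome size | loci | 50–2,500 |
| `mu` | mutation rate | per locus per generation | 1e-4 (1e-3 at reduced scale) |
| `U` | genome-wide mutation rate | per generation; `U = mu·g` | 0.01–0.25 |
| `s` | selection per mutation | dimensionless, `[0, 1]` | 1e-3–5e-3 |
| `lambda` | LGT rate | probability per individual per generation | 0, 0.01, 0.1 |
| `L` | recombination length | contiguous loci, `[1, g]` | 1–`0.2g` |
| `generations` | run length | generations | 1e4–1e5 |

Exactly one of `mu` / `U` is supplied; the `mutation_regime` records which
is held fixed when `g` varies across a sweep. The *per-locus* regime
(`U = μg` grows with `g`) is the biologically natural one; the
*genome-wide* regime (constant `U`, so `μ = U/g` shrinks) is an artificial
control that isolates the intrinsic decline of LGT's efficacy with genome
size from the growth of the mutational target. `L` accepts the fraction
rule `"0.2g"`, resolved as `max(1, round(0.2·g))` — e.g. 500 loci at
`g = 2500`.

## Measures and their conventions

* **Fixed mutation levels.** `Δm` counts `Σ_i min_j z_i(j)`: a locus that
  fixes repeatedly during a long run contributes every fixed level. The
  alternative reading — count each fixed locus once — is available as
  `fixation_rates(..., count = "loci")`; the two differ only on long runs
  with high mutation rates. The identity
  `per_locus_rate × g = genome_wide_rate` holds exactly.
* **Censoring.** A replicate with no fixation reports `text = NA` with a
  censoring flag; aggregation uses `text_effective` (the run length, a
  lower bound) and reports the censored fraction per grid point, so
  censoring is visible rather than silently absorbed into means.
* **Compartment normalisation.** Core and accessory fixed counts are
  normalised by their *own* locus numbers (per-locus rates comparable
  across compartments); `normalise = "total_g"` divides both by `g`
  instead. An empty compartment reports `NA`, not zero.

## Analytic predictions

`equilibrium_llc_size(N, U, s) = N·exp(−U/s)` is the deterministic
mutation–selection-balance expectation of the LLC size (the zero class of
the Poisson load distribution with mean `U/s`). Under the per-locus
regime `U = μg`, so the expected LLC declines exponentially with genome
size — `log n0` is linear in `g` with slope `−μ/s`
(`predicted_severity_curve()`). The simulation agrees with this
equilibrium in the slow-clicking regime: at `N = 2000`, `U = 0.05`,
`s = 0.05` (`n0 ≈ 736`) the time-averaged simulated LLC between burn-in
and the first click falls within a few percent of the prediction (the test
suite enforces 15%). When `n0` approaches one individual the ratchet
clicks rapidly and the equilibrium is only a scale reference.

## Numerical and implementation choices

* **Two engines, one trajectory.** Every life-cycle step exists as a
  documented R function (`selection_step()`, `mutation_step()`,
  `lgt_step()`, `advance_generation()`), and the production engine is a
  compiled loop (Rcpp). Both draw from R's RNG in an identical call
  sequence — selection samples parents by inversion of the cumulative
  fitness profile against `runif(N)`, mutation uses `rpois` then uniform
  locus draws, LGT uses `runif(N)` event draws then per-event donor/start
  draws — and fitness is accumulated in plain double precision in the
  same column order in both (the C++ is compiled with FMA contraction
  off). Consequently the two engines are *bit-identical* for a fixed
  seed, which the test suite asserts across event orders and fitness
  forms; the R engine additionally retains full state histories for
  brute-force verification of the fixation tracker.
* **Seeding.** A replicate batch uses seeds `base_seed + (i − 1)`; sweep
  grid point `k` offsets its batch by `(k − 1)·replicates`. Every output
  row carries its seed, and the metadata echo suffices to reproduce
  tables byte-for-byte.
* **Degenerate inputs.** `U = 0` and `λ = 0` are legal (the neutral and
  clonal limits); all-zero fitness terminates a replicate with an
  `extinct` flag; `L > g` grid points are skipped with a warning rather
  than failing a sweep.
* **Cost.** A generation costs O(`N·g`) memory traffic; the column-minima
  scan short-circuits at the first zero and is skipped entirely while the
  LLC is non-empty. Runs of `N·g ≈ 1e5` for 1e4 generations take on the
  order of a second.

## Experiment presets and reduced scale

`desk_preset()` provides the four experiment families — extinction time
vs genome size, fixation rate vs genome size under each mutation regime,
and the core/accessory split — at two scales. The `"paper"` scale records
the full-scale parameterisations (`N = 5e3`–`1e4`, `s = 1e-3`,
`μ = 1e-4`, 50 replicates, 1e4–1e5 generations); these are multi-hour
computations. The `"desk"` scale, which the test suite and the acceptance
script use, reduces the problem while preserving each experiment's
comparative structure:

* `N` is reduced to 200–500 with the selection intensity `N·s` held at
  its full-scale value (`s = 0.01` at `N = 500` plays the role of
  `s = 1e-3` at `N = 5e3`), since drift–selection balance, not raw `s`,
  governs the ratchet;
* `μ` is raised to `1e-3` so fixations accumulate within runs of 1e4–2e4
  generations;
* genome sizes span 50–200 with `L ∈ {1, 5, 0.2g}`, 10 replicates per
  grid point;
* the core/accessory experiment keeps the full-scale compartment
  coefficients (`g_core = 50`, `s_core = 0.005`, `s_accessory = 0.001`)
  and uses `N = 200`, where `s_core ≈ 1/N` leaves the core slowly
  clicking and the accessory (`s_accessory ≪ 1/N`) nearly neutral — the
  regime that separates the compartments.

At this scale the qualitative orderings are stable across independent
seed batches: extinction time falls from `g = 50` to `g = 200`; LGT at
`λ = 0.1, L = 0.2g` lengthens extinction times several-fold; genome-wide
fixation accelerates with `g` under the per-locus regime but not under
constant `U` with `L = 0.2g`; and the accessory genome out-accumulates
the core in every replicate, with LGT cutting core fixation further.

## What the simulations do and do not show

All data in this package are self-generated by the model; there is no
empirical input. The simulator emulates a finite asexual population with
unlinked deleterious mutation counts, segmental homologous recombination
from a one-generation eDNA pool, and constant population size. It does
not emulate: back-mutation or beneficial mutation; epistasis; plasmid- or
phage-mediated transfer; ectopic recombination and mobile elements;
variation in `N` (so mutational meltdown appears only as the all-zero
fitness edge case); nucleotide-level sequence identity requirements for
recombination; or evolution of `λ`, `L`, or genome size themselves.
Passing tests therefore demonstrate the internal consistency of the model
and the robustness of its comparative claims at reduced scale — not
quantitative predictions for any real organism, and not the figures'
absolute values at full scale, which the `"paper"` presets exist to
recompute on cluster time.

## Known limitations

* Extinction times at reduced `N` are much shorter than at full scale;
  only orderings, not magnitudes, transfer.
* `text_effective` aggregates censored replicates at their run length;
  grid points with a high censored fraction understate the true mean
  extinction time (the fraction is reported alongside).
* The multiplicative fitness form requires `s < 1`; the linear form's
  zero-clamp makes very high loads selectively equivalent.
* The compiled engine holds two `N × g` integer matrices in memory;
  `N·g` beyond ~1e8 entries is impractical on a workstation.
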