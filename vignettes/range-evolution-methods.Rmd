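---
title: "Models and methods behind searange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind searange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searange)
```

## The problem

Extant marine biodiversity is distributed very unevenly across the global
ocean's biogeographic realms. To ask *how* that pattern accumulated — how
much of each realm's diversity arose in place, how much immigrated, where
emigrants went, and where lineages were extirpated — one needs to
reconstruct the geographic range history of many dated clades and then count
the biogeographic events that histories imply. `searange` implements that
whole chain for a small set of realms (the canonical nine: NC, CI, CP, EA,
EP, SC, WA, WI, NP): range-evolution models, their likelihoods, stochastic
mapping, the dispersal-multiplier machinery that injects paleogeography, and
the downstream accounting and statistics.

## The model family

A species range is a non-empty subset of the realm set, encoded as a bitmask.
Along a branch, ranges evolve by a continuous-time Markov chain with two
anagenetic moves:

* **dispersal** — realm `k` is added to range `R` at rate
  `d * sum_{i in R} M[i, k]`, where `M` is the dispersal multiplier matrix of
  the geologic stratum the branch segment lies in;
* **extirpation** — any occupied realm is lost at rate `e`.

The empty range is absorbing (a globally extirpated lineage cannot recover).
At each node, a cladogenetic event assigns daughter ranges. The three bases
differ only in which events they allow: DEC permits narrow sympatry, subset
sympatry and narrow vicariance (one daughter confined to a single realm);
DIVALIKE permits narrow sympatry and vicariant splits of any size;
BAYAREALIKE only copies the ancestral range to both daughters. The `+J`
variants add founder-event speciation: one daughter jumps to a single realm
outside the ancestral range, weighted `j` times the mean multiplier from the
occupied realms to the destination, so founder jumps honor the same
paleogeographic scenario as anagenetic dispersal. Per-event weights `y`, `s`,
`v` are fixed at 1 (the family's convention); only `d`, `e` and, for `+J`
models, `j` are estimated, giving 2 or 3 free parameters.

The likelihood is computed by pruning over the range state space, with each
branch split at stratum boundaries and propagated by the matrix exponential
of that stratum's generator, and cladogenetic mixing applied at nodes using
the stratum containing the node age. The root is averaged over all non-empty
states (flat prior; the model family has no canonical root prior and a flat
one keeps nested models comparable). Per-branch rescaling prevents underflow
on large trees.

### Numerical choices

Matrix exponentials use a validated eigendecomposition fast path (one
decomposition per stratum per likelihood evaluation, reused across branches)
and fall back to `Matrix::expm` (scaling-and-squaring) whenever the
eigenbasis is ill-conditioned or the result fails stochasticity checks
(row sums within 1e-8 of 1, entries above -1e-8). Optimization is
multi-start L-BFGS-B on `(log d, log e, j)` with bounds `d, e` in
`[1e-9, 5]` /Myr and `j` in `[0, 2.99999]`; five starts by default, three in
the heavier test fixtures, which on pilot fixtures reproduce the optimum to
well under 1e-3 log-units across seeds. The state space may be capped
(`max_size`) for speed at high realm counts; the default is uncapped.

## Stochastic mapping

Given a fitted model, `sample_history()` draws complete histories
conditional on the tip data: node states from the conditional posteriors,
one cladogenetic event per node (proportional to event probability times
daughter-subtree likelihoods), and anagenetic paths along branches by
endpoint-conditioned uniformization (jump count drawn from the
Poisson-weighted power series of the uniformized chain, then states
backward-filtered so the path is guaranteed to hit the sampled endpoint; a
retry guard of 1,000 attempts covers numerically degenerate corners).
Replaying any sampled log reproduces every branch endpoint exactly — this
invariant is asserted in the tests over hundreds of seeded maps.

Event classification attributes each event to realms. A dispersal into `k`
from range `R` counts one immigration into `k` and one emigration split
`1/|R|` over the occupied realms (alternatives: all weight on the
realm with the largest multiplier toward the destination, or one source
realm at random — the fractional rule is the default because it is
deterministic and conserves totals under any occupancy). In-place events
(narrow sympatry, widespread copying) are split across the sympatric range;
subset sympatry is credited to the nested single-realm daughter; vicariance
is split across the ancestral realms. Every dispersal-like event therefore
contributes exactly one immigration and one emigration — totals are
conserved through attribution, which is what makes the interchange matrices
and the process shares internally consistent.

## Paleogeography and dispersal multipliers

Rotated realm seed points (the output of a tectonic reconstruction; rotation
itself is out of scope and treated as input) are extrapolated over the
epoch's water mask by nearest-seed assignment (spherical Voronoi), realm
centroids are taken as spherical means, and the shortest over-water path
between centroids is computed by Dijkstra on the 8-connected water-cell
lattice with great-circle edge weights and longitude wraparound. Distances
are min-max normalized and subtracted from one. Choices the source
procedure leaves open, and how they are resolved here:

* normalization is per epoch by default (`normalize = "global"` pools the
  maximum across epochs instead);
* unreachable pairs get 1.5 times the largest finite distance before
  normalization, i.e. near-zero but well-defined multipliers;
* an all-equal distance matrix carries no information and maps to all-ones
  multipliers rather than all-zeros (flagged via an attribute);
* an optional floor `eps` (0 by default, 0.01 typical) keeps the farthest
  pair's dispersal possible in the likelihood;
* centroids use spherical (unit-vector) means; antipodal degeneracy is an
  error rather than a silent pole.

Stratification presets: 5-Myr strata to 45 Ma for cetacean-aged trees,
10-Myr strata to 140 Ma for older groups, both closed by a cap stratum to
360 Ma, which must exceed the root age of any analyzed tree.

## Event accounting

Tallies average per-map counts across stochastic maps and sum across clades.
Richness standardization divides per-realm counts by extant richness
(realms with one or fewer species are excluded — a per-species rate is
meaningless there) with a configurable scale factor; the sources motivating
this package print both a per-1,000 and a per-10,000 convention, so the
scale is an explicit argument rather than a constant. Rolling series use
1-Myr bins over the most recent 65 Ma with a centered 3-bin window — the
"3-Myr window over 1-Myr bins" reading is the only one consistent with
reporting events per million years — and partial windows average over the
available bins. Lineages-through-time per realm are reconstructed by
replaying each map and counting, in 0.1-Myr bins, the lineages whose range
contains the realm, summarized by the mean and the 2.5/97.5% quantile
envelope across maps. Interchange networks can be thinned to the top
quartile of positive edge weights (linear-interpolation quantile, ties at
the threshold kept).

## Predictors and statistics

Per-realm predictors: Faith's PD; phylogenetic endemism with branch ranges
defined as the union of descendant species' realms; weighted endemism; fair-
proportion evolutionary distinctiveness summarized by median and SD; mean
species range size; centroid isolation (great-circle by default, chord
optionally — the "straight-line" reading of Euclidean distance on a sphere);
continental shelf area as the 0–200 m depth band with the 200 m boundary
included; and realm area/body size supplied as data. The collinearity screen
removes, iteratively, one member of the most correlated pair above |r| = 0.7
— the member with the larger mean |r| against everything else, ties dropping
the later column. The original procedure resolved such pairs by judgment;
a deterministic rule is used here instead and is labeled as a substitute,
not a reconstruction.

The statistical battery: paired Wilcoxon signed-rank tests across 3-Ma
rolling timebins (zero differences dropped; exact p by generating-function
enumeration up to n = 25, which stays exact under tied average ranks, normal
approximation with continuity and tie corrections beyond); GLS with AR1
errors and a `timebin * epoch` interaction around the 23.03 Ma Miocene
boundary (independent-error fallback on convergence failure, flagged);
LTT regressions on log lineage counts so the interaction tests acceleration
beyond the expected exponential; and mixed models with z-scored predictors,
random intercepts for realm and/or taxon (both specifications are supported
because the source material describes both), Wald 95% intervals and
Satterthwaite p-values.

## The synthetic-data generator

`sim_tree()` draws birth–death trees conditioned on the tip count;
`sim_ranges()` evolves ranges forward with a Gillespie simulator that calls
the *same* generator and event-table builders as the likelihood (a single
source of truth, so simulator/inference transcription bugs are structurally
impossible), logging every event with time and realms. Lineages absorbed
into the empty range make the attempt invalid (tips must be non-empty) and
the whole clade is resampled, up to a cap — this conditions the data on
survival and slightly depresses realized extirpation at high `e`, a
documented bias of the resampling design. `sim_paleogeography()` drifts
realm seed points linearly and can insert meridional land bars (a closing
seaway) from a chosen epoch onward; `make_benchmark_bundle()` assembles a
desk-scale analogue of a multi-group global analysis (by default 4 pseudo-
groups of 5 clades, 10–50 tips each, over 5 realms).

What the generator emulates: clade sizes in the 10–100 range used by
split-tree pipelines, stratified dispersal scenarios, founder-dominated and
anagenetic-dominated regimes. What it does not: real continental geometry,
range-size heterogeneity induced by traits, fossil signal, or sampling
artifacts of range polygons. Passing tests therefore demonstrate internal
correctness and recoverability under the model's own assumptions, not the
fidelity of any empirical reconstruction.

## Problem sizes and test design

The test and acceptance fixtures are sized for a single CPU: exhaustive
likelihood oracles run on 2–5-tip trees over 3 realms (50 random parameter
draws across all six models, agreement to 1e-8); endpoint-conditioned
transition counts are checked on a 2-state branch against a numeric
closed form with 10,000 maps; parameter recovery uses one 150-tip, 4-realm
clade (Yule birth rate 0.5/Myr, root age around 10-15 Ma); founder-model
selection uses 20 replicate 25-tip clades over 3 realms. Because the
forward simulator conditions on non-empty extant tips, occasional tree
shapes admit no such outcome within the resample cap; fixture generation
redraws the tree with the next seed when that happens, which is part of the
same conditioning-on-survival design.

## Known limitations

* Under DEC, the maximum-likelihood extirpation rate is weakly identified:
  narrow vicariance can explain single-realm tips nested inside widespread
  clades without invoking any extirpation, and on forward-simulated data
  with moderate `e` the profile likelihood typically decreases in `e` so the
  MLE sits at the lower bound. This is a property of the model family, not
  of the optimizer; the package's tests document it by showing that the same
  pipeline recovers `e` accurately under BAYAREALIKE, where no cladogenetic
  pathway can absorb the signal. Per-realm extirpation counts from
  stochastic maps inherit this caveat under DEC-family best fits.
* Only extant lineages enter the model, so "extinction" means realm-level
  extirpation of surviving lineages; fully extinct clades are invisible.
* Clade splitting retains the stem branch to each clade's MRCA; whether to
  keep stems is genuinely open, and keeping them preserves total tree depth
  for the time-stratified machinery.
* The geography threshold rule exposes both denominator conventions (all
  occupied cells vs in-realm cells) because the source procedure does not
  pin one down; the default keeps out-of-realm cells in the denominator.

## A worked micro-example

```{r example}
r <- realm_set(c("A", "B", "C"))
dmm <- uniform_dmm(r)
tr <- sim_tree(20, lambda = 0.6, seed = 7)
sim <- sim_ranges(tr, r, dmm, "DEC+J", model_params(d = 0.05, e = 0.01, j = 0.6),
                  seed = 8)
fits <- lapply(c("DEC", "DEC+J"), function(m)
  fit_range_model(sim$clade, dmm, m, n_starts = 3, seed = 1))
model_select(fits)

maps <- run_bsm(attr(model_select(fits), "best"), n_maps = 10, seed = 2)
tl <- tally(maps, r)
round(tl$event_table, 2)
process_shares(tl$type_totals[tl$type_totals > 0])
```
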