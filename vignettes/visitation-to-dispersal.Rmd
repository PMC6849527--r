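---
title: "From visitation networks to seed-dispersal networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From visitation networks to seed-dispersal networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispnet)
```

## The problem

Plant–frugivore networks are usually sampled by watching birds visit
fruiting plants. A visit, however, is not a seed-dispersal event. A
frugivore can swallow the fruit whole and defecate or regurgitate viable
seeds (a legitimate disperser and true mutualist), peck the fruit for pulp
while the seed drops below the parent (a pulp pecker — an exploiter), or
crack and digest the seed itself (a seed predator — an antagonist).
Treating a visitation network as a seed-dispersal network therefore mixes
interactions with opposite consequences for plant fitness.

dispnet labels every link of a quantitative visitation network with one of
the three functional outcomes, removes the non-mutualistic links, and
quantifies what that removal does to network- and species-level structure.
Because many structural metrics react mechanically to network size, raw
changes are complemented by Δ-transformed changes under two quantitative
null models, and the loss of dispersal service under bird extinction is
probed with a topological coextinction model. Directional hypotheses (for
example, nestedness should *increase* when antagonistic links are removed)
are tested with one-tailed paired Wilcoxon tests, rank stability with
one-tailed Spearman tests, and the batch of tests is guarded against
multiple-testing artefacts with the exact Bernoulli-process probability of
obtaining the observed number of significant results.

## Data model

A `labeled_network` is a plants x birds matrix of non-negative integer
visit counts, with one outcome label (`seed_dispersal`, `pulp_pecking`,
`seed_predation`) per nonzero cell and a provenance flag (`direct` or
`inferred`). Counts are integers because the null models condition on
integer marginals; networks recorded as visitation *rates* are converted by
multiplying each rate by the time spent sampling that plant and rounding to
the nearest whole number. "Nearest" is ambiguous at exact halves, so the
package commits to round-half-up: `rate_to_counts(0.25, 10)` is 3, always.

Where a pairwise outcome has no direct natural-history record,
`infer_outcome()` transfers labels from (1) the same bird's interactions
with congeneric plants, then (2) its interactions with plants of the same
fruit type and seed-size class. Within a rule, conflicting labels are
resolved by majority; residual ties go to the less mutualistic outcome
(predation over pecking over dispersal), a deliberately conservative stance
about crediting dispersal service. The congener-before-traits precedence is
a package convention — field experts used both cues without a published
ordering — and inferred labels stay flagged in the provenance layer.
Direct records that contradict each other are an error at read time, never
voted away.

Pruning (`prune()`) zeroes the targeted cells (all non-mutualistic links,
or only predation links, since pulp peckers are better seen as cheaters
than antagonists). Species whose totals drop to zero are *kept* in the
matrix and listed as dropped: degree and interaction frequency legitimately
become zero for them (excluding those zeros would understate mean change),
while specialization, strength and resilience become missing, and the
network-level metrics simply ignore empty rows and columns.

## Metrics

**Size** counts species with at least one link. **Weighted connectance** is
quantitative linkage density — the marginal-weighted mean of each species'
effective partner number `exp(H)`, with `H` the Shannon entropy (natural
log) of its interaction vector — divided by size; a uniformly filled matrix
of any shape scores exactly 0.5. **Weighted nestedness (WNODF)** ranks rows
and columns by decreasing marginal totals and scores each strictly ordered
pair by the share of the poorer line's links that are outweighed by the
richer line; ties score zero. Note one convention choice: the package ranks
and ties by *marginal totals* everywhere, whereas some implementations rank
by binary fill and break ties by totals — the two agree whenever the fill
and total orders coincide, which the test suite exploits for an independent
cross-check against vegan.

**H2'** standardizes the two-dimensional entropy of the matrix between the
maximum given the marginals (the continuous product distribution, whose
entropy is the sum of the marginal entropies) and a minimum from a greedy
integer packing that repeatedly loads `min(row remainder, column
remainder)` onto the currently largest pair. Exact integer entropy
minimization is a hard combinatorial problem; the greedy packing is
validated against exhaustive enumeration over all tables with the same
marginals on every small matrix the test suite can afford, and the ratio is
clamped to [0, 1] because the continuous maximum slightly exceeds what
integer tables can reach.

**d'** measures how far a species' partner use deviates from partner
availability (Kullback–Leibler divergence of use from availability),
standardized by integer-constrained extrema: the maximum concentrates the
species' whole total on its rarest partner; the minimum comes from
largest-remainder apportionment proportional to availability polished by
single-unit moves, which is exact because the objective is separable convex
on the integer simplex. Availability is always computed from the marginals
of the *state being analysed* (pruned availabilities for pruned networks):
the analysis recomputes every metric on the post-removal network, and using
stale availabilities would mix states. A species with a single available
partner has no freedom and scores 0; a species with no links has no value
at all. **Species strength** of a bird sums, over plants, the fraction of
each plant's visits it accounts for; strengths across birds always sum to
the number of linked plants, which the tests use as a conservation law.

**Modularity** is weighted Barber modularity `Q`, the within-module excess
of interaction weight over the marginal-product expectation, maximized by a
label-propagation-plus-agglomeration search (LPAwb+ family). The
implementation alternates guild-wise exact block reassignments (each sweep
can only increase Q), then greedily merges module pairs while any merge
helps, and repeats. The search is stochastic only through its restarts; the
seed is recorded in every report. One run per calculation is the default,
mirroring standard practice, with `repeats` available to probe the spread
(on every small matrix enumerable by brute force, one seeded run with ten
restarts attains the exhaustive-partition maximum). Convergence knobs
(minimum Q gain `1e-10`, sweep cap `1e4`) are exposed rather than baked in,
since the field literature does not pin them.

## Null models and Δ-transformation

The Patefield model redistributes the `m` interaction tokens uniformly at
random conditional on both marginal totals: the implementation pairs the
row-label tokens with a random permutation of the column-label tokens,
which samples exactly the multivariate-hypergeometric table distribution of
the classic algorithm. `quasiswap_count` additionally conserves the number
of nonzero cells (connectance) via marginal-preserving 2x2 updates; the
package delegates this step to vegan's `quasiswap_count` algorithm — the
implementation in standard use — and guarantees the conservation contract
rather than bit-equality with any particular swap schedule. Δ-transformed
metrics subtract the ensemble mean (1,000 samples by default) from the
observed value; only Δ is reported, not z-scores, because ensemble
standard deviations are not part of the reporting convention this package
follows. Metrics that are themselves stochastic (modularity) are re-run per
sample with seeds derived from a recorded stream.

## Coextinction model

Birds are removed from least to most total interaction frequency — an
abundance proxy, on the argument that scarce species go first under
anthropogenic pressure — with ties broken by species id (a seeded
randomized-tie mode exists for sensitivity checks). A plant fails once it
has lost at least 75% of its interaction frequency; the comparison is
inclusive (`lost >= 0.75`) and pinned by tests because integer edge cases
differ between inclusive and exclusive readings. Robustness is the
trapezoidal area under the survival curve sampled at every removal step,
and per-plant resilience is the fraction of birds that had to be removed
before that plant failed. When a pruned state is analysed, the removal
order is recomputed on the pruned network (the alternative — reusing the
original order — is available via the `removal_order` argument, since
either reading is defensible).

## Paired tests and multiple testing

Each metric carries a hypothesized direction of change (size down,
connectance up, nestedness up, specialization down, modularity down,
robustness down; plant degree, frequency, d' and resilience down; bird
strength up), and the Wilcoxon signed-rank test is run one-tailed in that
direction. Zero differences are dropped (the classic convention of the
software heritage this analysis follows, not Pratt's), absolute differences
are mid-ranked, and for up to 25 informative pairs the p-value is exact —
computed by convolution over the doubled mid-ranks, which is identical to
enumerating all 2^n sign assignments. Spearman tests are one-tailed against
the positive alternative, encoding the null of unchanged ranks; a
non-significant result flags a rank change. For n <= 8 the Spearman p is
exact by full permutation enumeration. The Bernoulli-process probability
`choose(N, K) * alpha^K * (1-alpha)^(N-K)` summarizes how surprising K
significant results among N tests would be under independence; counting
uses alpha = 0.05. Species-level tests run both pooled across networks and
per network; the summary tables average per-network mean changes (so large
networks do not dominate) and compute coefficients of variation across all
species pooled, with the sample standard deviation.

## The synthetic generator

Real deposits of all seven field networks are not bundled, so the package
generates labelled networks with the structure the analysis assumes, and
every pipeline stage is tested against those. The generator is a structural
emulator, not an estimator: no attempt is made to fit any particular
empirical network. What it emulates, and why:

* **Skewed interaction frequencies.** Lognormal abundances on both guilds
  (sd-log 1 for plants, 2 for birds) with Poisson counts whose intensity is
  the abundance product times lognormal cell-level niche noise (sd-log 1).
  The niche noise matters: a pure rank-one product makes a single hub bird
  dominate every plant, which no field network shows. Defaults give ~20
  plants x 25 birds, fill near 0.3, totals in the low thousands and maximum
  cells in the hundreds — the scale of the field data the analysis targets.
* **Bird roles.** 52% pure dispersers, 18% pulp peckers, 18% seed
  predators, 12% mixed-role, leaving roughly a third of birds with no
  dispersal link, as observed in European assemblages. Seed predators can
  only handle plants whose latent seed size falls under their bill
  threshold; mixed-role birds disperse seeds *above* their gape threshold
  (large, hard-coated seeds pass the gut intact) and destroy smaller weaker
  ones, so their outcome genuinely differs between plant species.
* **Non-mutualists matter more qualitatively than quantitatively.** Counts
  on non-mutualistic links are thinned beyond the first visit by a damping
  factor (0.12), and non-mutualistic intensity couples to fruit-crop
  abundance only with exponent 0.4 at 0.45 of the mutualistic level —
  fleshy fruit is a side resource for granivores and insectivorous pulp
  peckers, whose fruit choice follows seed and pulp traits more than crop
  size, and whose fleshy-fruit niche is narrower than a disperser's. Under
  the defaults the non-mutualistic share of links averages ~0.35 (within
  the 21–48% field envelope for ~95% of networks) while the share of total
  frequency averages ~0.09 (within the 5.7–24% envelope), and the frequency
  share sits below the link share in every generated network.
* **Degenerate draws.** A species that draws no links is connected to its
  best admissible partner with a single visit, so every listed species
  participates; a draw with no links at all is resampled up to a cap.

What the generator does *not* emulate: family-level taxonomic structure
(the concentration of dispersal in thrushes and warblers), rate-sampled
networks, overdispersion beyond Poisson (available via the
`overdispersion` parameter but off by default), and mammal frugivores.
Passing directional-recovery tests on these synthetic ensembles therefore
shows that the pipeline detects the structural signature the generator
encodes — it is not a validation against any particular field dataset.

## Numerical choices and degenerate inputs

Metrics are undefined (`NA`, not an error) on empty networks, and WNODF on
anything smaller than 2x2; Δ-transformation skips undefined null samples
and warns past 10% skipped. H2' and d' are clamped to [0, 1]. The exact
Wilcoxon branch switches to a continuity-and-tie-corrected normal
approximation above 25 pairs; Spearman switches to the t approximation
above n = 8. All stochastic stages consume seeds derived from one master
seed, every derived seed is logged, and a rerun of `run_analysis()` with
the same configuration is bit-identical (wall-clock time is deliberately
kept out of the log file).

## Problem sizes used by the test suite

The exhaustive oracle checks cover all integer matrices up to 3x3 with
total at most 8 (deduplicated under row/column permutations, which the
metrics are invariant to), with modularity checked against the maximum over
all set partitions of up to six species. Null-model conservation is checked
on 1,000 samples of a 10x10 matrix, strength conservation on 10^4 random
matrices, test calibration on 1,000 replicates of 20 pairs, and directional
recovery on 50 master seeds of the default seven-network ensemble. These
sizes were chosen so the whole suite runs comfortably on a laptop while
still enumerating every case the brute-force oracles can reach.

## Limitations

Outcome labels are categorical; real outcomes grade into each other (the
same bird and plant can interact both ways), and fruit-level mixed
outcomes are out of scope — one label per link. The analysis concerns the
fruit-removal stage only: true dispersal additionally depends on where
seeds land and whether seedlings establish, so even a perfectly pruned
network is a proxy for dispersal service, not a measurement of it.
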