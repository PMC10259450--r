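---
title: "Classifying speciation mode in sky-island radiations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying speciation mode in sky-island radiations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisterdiv)
```

This vignette is the package's own account of the science it implements:
the comparative framework for deciding whether sister species in
island-like habitat diverged by geographic isolation or by parapatric
ecological divergence, the phylogenetic-signal and ancestral-range models
around it, and the numerical and design choices a maintainer should know
about.

## The sister-pair framework and its assumptions

A cherry of an ultrametric chronogram — two tips that are each other's
closest relatives — is treated as the product of one recent speciation
event. For each pair the package asks two questions. *Where do the sisters
live?* Occurrence records are assigned to habitat-island polygons; sharing
at least one island makes the pair sympatric, occupying disjoint island
sets makes it allopatric. *Did their niche diverge?* A functional trait
measured per specimen (leaf area in mm², a standard proxy for the
eco-physiological niche of Andean plants) is compared between the sisters
with a rank test. The four combinations map to a category:
allopatric + similar traits is geographic isolation with niche
conservatism; allopatric + different traits is geographic isolation with
subsequent local adaptation; sympatric + different traits is parapatric
ecological divergence; sympatric + similar traits is inconclusive, because
sympatric speciation, secondary contact after allopatric speciation, and
divergence in an unmeasured trait are indistinguishable there.

The framework inherits four substantive assumptions, documented here as
caveats rather than enforced by code: the trait must be a reasonable niche
proxy; the chronogram must be the best available species tree (unsampled
species are handled by the substitution mechanism below, which rests on
taxonomic judgement); the habitat system should be young enough that
carrying capacity has not been reached; and modern ranges must be
representative of the ranges at divergence. The last assumption is why the
framework is restricted to *recent* events — cherries, not deep nodes — and
why the package deliberately does not attempt to separate vicariant from
dispersal-mediated allopatry, although it reports range asymmetry as a
cautious dispersal signature.

Missing species: if species C is absent from the tree and the taxonomic
literature proposes C as most similar to sampled species A, the
phylogeny-derived pair (A, B) is replaced by (A, C); several proposals for
the same sampled species accumulate as *alternates* on a single pair. A
pair with alternates counts once in every tally; if its alternates ever
disagreed on category, the pair would be flagged and counted as
inconclusive. Pairs without trait data classify on distribution alone —
this rule mirrors the behaviour visible in the published case-study table
that ships with the package, where rows lacking leaf data still carry a
distribution-driven classification.

## Grids, islands and the distribution call

Grid metrics complement the island call as an independent line of
evidence. Occurrences are rasterised into half-open cells
`[x, x + s) × [y, y + s)` anchored at integer degrees; the defaults
`s = 0.05°` and `s = 0.1°` are the two published resolutions. Range size is
the occupied-cell count (cell counts, not km²: at páramo latitudes the two
are proportional enough that the published areas are informational only).
Overlap divides the shared-cell count by the smaller range; asymmetry
divides the larger range by the smaller. The grid origin is not stated in
the source material, so the package fixes it at (0, 0): with an anchored
origin and half-open cells every result is bit-stable, and at the 0.1
precision at which overlaps are reported the origin choice is negligible.

Island membership is point-in-polygon (even-odd ray casting) with boundary
points counted inside — occurrence records digitised on an island margin
should not silently fall off the island. Records outside every polygon are
flagged and excluded from island sets but retained for gridding; a species
with no island membership and no flank data yields an *undetermined* call,
which propagates to an inconclusive classification rather than an error.
The one deliberate asymmetry between the two lines of evidence: the island
call drives the classification, the grid metrics are computed alongside as
the cross-check. The grid equivalent of allopatry is strict `O = 0` — no
tolerance, since a single shared cell is positive evidence of contact.
Forest-belt species need one more rule: two sisters can co-occur on a
mountain while occupying disjoint slopes below the open-páramo line, so
when both species carry the forest habitat tag and their flank labels are
disjoint on every shared mountain, the pair is called allopatric.

## The rank test

The published methods name the signed-rank (paired) test, but sister
species contribute independent leaf samples of unequal provenance — there
is no natural pairing of leaf *i* of one species with leaf *i* of the
other. The package therefore defaults to the two-sample rank-sum
(Mann–Whitney) test and offers the paired signed-rank variant behind
`paired = TRUE` for genuinely matched designs. The exact null distribution
is used for tie-free samples with combined n ≤ 16; larger or tied samples
use the normal approximation with midranks, tie-corrected variance and
continuity correction. The test suite checks the exact branch against an
independent enumeration oracle over all rank assignments and checks the
two branches against each other at the crossover size. Because rank tests
are invariant under strictly monotone transforms, the log transform cannot
change any verdict — it matters only for the reported summaries (species
means of log leaf area). The significance level is fixed at α = 0.05 per
pair, uncorrected: the shipped case-study table flags p = 2.5e−9 as
significant and p = 0.1663 as not, which is consistent only with
uncorrected per-pair testing. Percentages in tallies are rounded half up to
one decimal (1/15 reports as 6.7%).

## Pagel's λ by profile maximum likelihood

Under Brownian motion the tip covariance equals shared root-to-tip path
length; λ rescales the shared (off-diagonal) part while leaving tip
variances unchanged, so λ = 0 is a star phylogeny and λ = 1 plain Brownian
motion. At fixed λ the root state and rate have closed-form GLS solutions

\[ \hat z_0 = \frac{\mathbf 1' C^{-1} x}{\mathbf 1' C^{-1} \mathbf 1},
\qquad
\hat\sigma^2 = \frac{(x - \hat z_0)' C^{-1} (x - \hat z_0)}{n}, \]

and the profile likelihood is maximised over λ ∈ [0, 1] by bounded search
with tolerance 1e−6 (values above 1 are not explored, matching common
practice; the ML σ² — not REML — is used throughout, and the closed forms
are verified against direct bivariate optimisation in the tests). The test
against λ = 0 is a likelihood-ratio test; since the null sits on the
parameter boundary, the reported p halves the χ²₁ tail (50:50 mixture with
a point mass at zero), with the plain χ²₁ p reported alongside because the
source material does not state its convention. Two conventions for
degenerate cases: a flat surface (star tree) reports λ = 0, and an
end-point check guards the bounded search against stalling just inside
λ = 1. Tips without trait data are pruned before fitting; at least four
tips are required.

## Range-evolution models

Ranges are non-empty subsets of an ordered area set (at most 10 areas; the
default is the eight páramo bioregions N, T, M, E, A, W, C, S), encoded as
bitmasks, with the empty range as an absorbing null state that anagenesis
can enter and cladogenesis cannot leave. Anagenesis is a continuous-time
Markov chain: expansion adds one unoccupied area at rate `d` per addable
area (per Myr), contraction removes one occupied area at rate `e`;
max range size defaults to all areas. The three model families share this
chain and differ at speciation nodes. DEC gives a single-area ancestor
identical daughters, and a widespread ancestor an equal-weight mixture of
subset sympatry (one daughter keeps the range, the other one of its areas)
and single-area vicariance; a two-area ancestor has exactly six ordered
events — four subset-sympatric and two vicariant — a fixture frozen in the
tests. DIVALIKE allows only vicariance for widespread ancestors, including
widespread-by-widespread splits. BAYAREALIKE copies the full range to both
daughters. The founder-event extension adds jump events (one daughter
keeps the range, the other colonises any single unoccupied area) with
per-event weight `j` against `(3 − j)/3` per base event, normalised per
ancestor state, so `j = 0` reproduces the base model exactly (checked to
1e−10).

The likelihood is Felsenstein pruning over states: per-branch transition
matrices `exp(Q t)` (eigendecomposition with a verified reconstruction,
falling back to a Padé/scaling–squaring matrix exponential when Q is
near-defective), cladogenetic mixing at nodes, per-node rescaling of
partial likelihoods against underflow on large state spaces, and equal
root weight 1 on every non-null state — the unnormalized uniform
convention, under which a data-free process scores probability 1;
normalization would shift every lnL by the same constant and cancel in
model comparison. Pruning is verified against a brute-force enumeration
over all node states and event choices on two- and three-tip fixtures to
1e−8. Fits use bounded multi-start optimisation (three starts;
`d, e ∈ [1e−12, 5]`, `j ∈ [0, 2.99]`), models are ranked by
`AIC = 2k − 2 lnL` with ties broken toward fewer parameters. The published
comparison table this package ships prints values that equal plain AIC
computed from its log-likelihoods, although its text mentions the
small-sample variant — AIC is therefore primary here and AICc is available
as an option. Ancestral states are exact marginals: the likelihood with
one node clamped to one state, divided by the unclamped likelihood — an
O(nodes × states) recomputation that is entirely adequate at the problem
sizes below. No dispersal multipliers, distance matrices or
time-stratification are implemented: the páramo's paleoelevations are
debated enough that the source analysis deliberately ran unconstrained
models, and this package keeps that scope.

## What the generators emulate — and what they do not

Every generator is a pure function of its arguments and seed. Trees are
pure-birth (`ape::rphylo`) and ultrametric. Islands are disjoint rectangles
on a jittered lattice, optionally grouped into bioregions — a deliberately
minimal geometry standing in for real páramo delineations, which are
irregular, nested and coastline-clipped. Occurrences are uniform draws
inside an island polygon; real collections are road- and access-biased,
spatially clustered and taxonomically uneven. Leaf areas are lognormal
(log-mean shift δ between diverged sisters, within-species log-SD σ),
matching the strictly positive, multiplicatively varying character of real
leaf measurements; the defaults δ = 2 log units and σ = 0.5 with 30 leaves
per species sit at the study design's sampling depth and at an effect size
(4 within-species SDs) typical of the between-habitat contrasts that
motivate the trait — the shipped case-study species means span roughly
5 log units between forest and open-páramo extremes. Traits on trees are
multivariate normal draws from the λ-scaled Brownian covariance. Range
histories are forward Gillespie simulations of the anagenetic chain with
cladogenetic draws at nodes; lineages that go globally extinct (null
range) kill the replicate, which is re-drawn and counted — the likelihood
models do not condition on survival, so heavy re-drawing at pathological
rates is surfaced to the user rather than hidden.

Passing tests on these generators therefore demonstrate the *inferential
machinery* — that the pipeline recovers known truth under its own model
assumptions at realistic effect sizes. They do not demonstrate robustness
to georeferencing error, collection bias, non-lognormal trait variation,
island delineation error, or model misspecification in the range models.

## Numerical choices and problem sizes

Ultrametricity is checked to 1e−6 × tree height and violations warn rather
than fail, because published chronograms carry rounding noise; polytomies
are rejected at parse. Exact duplicates among occurrences collapse, as do
multiple occurrences in one grid cell. The λ search tolerance is 1e−6; the
biogeographic optimiser runs three starts with box constraints given
above. All percentages round half up to one decimal.

The test suite and the analysis scripts size their simulations to run
comfortably on a laptop: λ recovery uses 50 replicates on 200-tip trees
per regime; rate recovery for the range models uses 20 replicates at 100
tips over a 4-area system (15 non-null states — a typical small bioregion
system, chosen once before the recovery protocol was run); the end-to-end
study uses 20 pairs with 30 leaves and 20 occurrences per species. The
analysis workflow (`analysis/01` – `analysis/04`) uses a 40-tip chronogram
and the same 4-area system.

## Known limitations

Two are worth stating plainly. First, the extinction/contraction rate of
DEC-class models is weakly identifiable: cladogenetic subset-sympatry and
vicariance already produce daughters with reduced ranges, so the
anagenetic contraction rate is routinely driven to its lower bound when
fitting DEC to data simulated under DEC with modest `e`. The package's
recovery tests document this honestly — the dispersal rate `d` is
recovered within a factor of 2 essentially always at the sizes above,
while `ê` collapses to the boundary; fitting BAYAREALIKE-simulated data
(where cladogenesis cannot absorb contraction) recovers both rates, which
localises the pathology in the model structure, not the estimator. Second,
the decision matrix's conserved/inconclusive cells depend on a
non-rejection at α = 0.05, so per-pair recovery for those scenarios is
bounded by 1 − α ≈ 95% by construction; aggregate recovery over a
20-pair study hovers at that level and individual replicates can dip
below it.

Beyond these: the framework cannot separate vicariance from dispersal
within allopatry; a single trait can miss ecological divergence along
unmeasured axes (the published framework itself flags this); and the
debate over founder-event (+J) parameters in likelihood biogeography —
whether the jump weight is comparable across models with different event
classes — is surfaced here only as documentation, with both base and +J
variants always fitted side by side.
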