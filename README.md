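# sisterdiv

Did two sister species split because a geographic barrier separated them, or
because they adapted to different niches side by side? In island-like
habitats — the archetype here is the Andean páramo, a chain of humid
high-elevation "sky islands" above the Andean treeline — the two hypotheses
leave different signatures in where the sisters live and what their
functional traits look like. `sisterdiv` implements a comparative framework
for classifying recent speciation events from three ingredients:

1. an ultrametric chronogram (source of sister pairs and their ages),
2. georeferenced occurrence records plus habitat-island polygons,
3. a morpho-ecological trait measured per specimen (leaf area, a proxy for
   the eco-physiological niche of Andean plants).

It is aimed at plant systematists and biogeographers studying radiations in
fragmented montane habitat, and at anyone who wants a tested, reusable
implementation of the sister-pair comparison, the phylogenetic-signal test,
and the discrete ancestral-range models that usually surround it.

## The framework

**Sister pairs.** Cherries (two-tip clades) of the chronogram are putative
products of single speciation events. Species missing from the tree are
handled by a substitution table: if C is unsampled and the taxonomic
literature proposes C as most similar to sampled A, the pair (A, B) from the
phylogeny is replaced by (A, C); competing proposals accumulate as
alternates on one pair, which counts once.

**Distribution.** Each pair is scored *allopatric* or *sympatric* on the
island framework — sharing at least one habitat island means sympatric, with
one exception: forest-belt species co-occurring on a mountain but restricted
to disjoint slopes (flanks) are allopatric. In parallel, occurrences are
rasterised on decimal-degree grids (0.05° and 0.1° by default, half-open
cells anchored at integer degrees) and two metrics are computed per pair:

- range overlap `O = |cells(A) ∩ cells(B)| / min(|cells(A)|, |cells(B)|)`,
  so `O = 0` is full allopatry and `O = 1` means the smaller-ranged sister
  lies inside its sister's range;
- range asymmetry `A = max(|cells|) / min(|cells|) ≥ 1`, large values being
  a (cautious) signature of dispersal/founder speciation.

**Trait divergence.** Leaf areas are log-transformed and compared per pair
with a two-sided rank-sum test (exact for small tie-free samples, normal
approximation with tie and continuity corrections otherwise); `p < 0.05`
means *different*.

**Decision matrix.** The distribution call and the leaf verdict classify the
speciation event:

| | leaf areas similar | leaf areas different |
|---|---|---|
| **allopatric** | geographic isolation | geographic isolation, subsequent ecological divergence |
| **sympatric** | inconclusive | parapatric ecological divergence |

Pairs without leaf data classify on distribution alone (allopatric →
geographic isolation, sympatric → inconclusive). Tallies report counts and
percentages over pairs.

**Niche conservatism.** Pagel's λ is fitted to species-mean log leaf area by
profile maximum likelihood (closed-form GLS for the Brownian rate σ² and
root state z₀ at each λ, bounded search on [0, 1]), with a
boundary-corrected likelihood-ratio test against λ = 0.

**Historical biogeography.** Likelihood models of geographic range evolution
over a set of bioregions: DEC, DIVALIKE and BAYAREALIKE differ in their
cladogenetic event classes (subset sympatry + single-area vicariance;
vicariance including widespread splits; full-range inheritance), each
optionally extended with founder-event ("jump") cladogenesis weighted by
`j ∈ [0, 3)`. Anagenesis is a Markov chain over subsets of areas (expansion
rate `d`, contraction rate `e` per area); tip-range likelihoods come from
Felsenstein pruning with per-branch matrix exponentials, and models are
ranked by `AIC = 2k − 2 lnL`. Ancestral ranges are reported as exact
per-node marginal probabilities.

A synthetic-data module (`simulate_study()`, `gen_tree()`, `gen_islands()`,
`gen_trait_bm()`, `gen_range_history()`) generates all of these inputs with
known ground truth, so the entire pipeline is testable offline.

## Worked example

The package ships the published summary tables of the *Linochilus*
(Asteraceae) páramo radiation — 15 sister pairs after substituting unsampled
species — as plain-TSV example data. Pushing the printed per-pair calls
through the decision matrix:

```r
library(sisterdiv)
tab <- study_pair_calls()
cats <- vapply(seq_len(nrow(tab)), function(i)
  classify_pair(tolower(tab$distribution[i]),
                pair_leaf_verdict(tab$p_value[i]))$category, "")
tally(data.frame(category = cats))
#> Speciation-mode tally over 15 sister pairs
#>   geographic_isolation   12 (80.0%)
#>   parapatric_ecological   1 (6.7%)
#>   inconclusive            2 (13.3%)
```

Twelve of fifteen recent speciation events (80%) carry the signature of
geographic isolation between páramo islands, one (6.7%) of parapatric
ecological divergence, two (13.3%) are inconclusive — the published result.
The same pattern emerges from a fully synthetic study with known truth
(`analysis/02_classify_pairs.R` reports 100% per-pair recovery at the
default effect sizes).

The numbered scripts under `analysis/` run the whole workflow on simulated
data and the shipped tables, writing their outputs under `results/`:

```sh
Rscript analysis/01_simulate.R        # datasets + ground truth
Rscript analysis/02_classify_pairs.R  # decision matrix + tallies
Rscript analysis/03_phylosig.R        # Pagel's lambda
Rscript analysis/04_biogeo.R          # six-model comparison + ancestral ranges
```

Stage 4, for instance, recomputes the published model comparison from its
log-likelihoods and parameter counts and ranks BAYAREALIKE+J first
(AIC 226.78) and DEC+J second (AIC 232.62).

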