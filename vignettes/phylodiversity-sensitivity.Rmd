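---
title: "Methods: phylodiversity metrics, nulls, and the five sensitivity experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylodiversity metrics, nulls, and the five sensitivity experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosens)
```

## The model

A community phylogenetic analysis in this package has three ingredients: a
rooted regional phylogeny with branch lengths (substitutions per site for
phylograms, time for chronograms), a binary sites-by-species occurrence
matrix over the pool of the tree's tips, and a null model. Per community we
compute Faith's PD (total branch length of the minimal spanning subtree,
including the root path by default), MPD (mean patristic distance over all
unordered pairs) and MNTD (mean distance to the nearest co-occurring
relative), and standardize each against a tip-label randomization null: the
topology, branch lengths, and taxon list are held fixed while the taxa are
shuffled across the tips. For one fixed community of k species this is
equivalent to drawing k of the N pool tips uniformly without replacement,
which is how the engine implements it (each replicate is one draw; all
requested metrics share the draws).

With R replicates, `ses = (obs − mean)/sd` (sd with denominator R − 1;
pinned by a test that reconstructs the null stream externally) and
`rank_p = (#{null ≤ obs} + 1)/(R + 1)`. Ties count as "≤", which is the
conservative direction for clustering claims. Classification is two-tailed:
clustered below α/2, overdispersed above 1 − α/2, random in between. We
report SES in the picante orientation (negative = clustered); `nri_nti()`
flips the sign for NRI/NTI axes.

Assumptions worth stating: presence/absence only (no abundance weighting);
a single fixed regional pool per analysis (the tip set of the supplied
tree); and exchangeability of tips under the null — the tip-shuffle null
asks "is this community a random draw from the pool?", nothing more.

## Tunable parameters

* `n_reps` (default 999): null replicates. 999 gives a rank-p floor of
  1/1000; 1,000-scale nulls are the field's convention.
* `alpha` (default 0.05, two-tailed): no universal convention exists for
  the tail split in this literature; we fix the conventional two-tailed
  0.05 and expose the argument.
* `include_root` (default `TRUE`): PD includes the MRCA-to-root path,
  matching the long-standing default of the picante implementation that
  most published numbers rest on.
* `min_taxa` (default 2): communities that fall below this after pruning
  or clade restriction are reported `NA`, never dropped silently —
  exactly the situation taxon subsetting creates.
* Subsampling: `random_subset()` is uniform; `family_proportional_subset()`
  allocates per-family quotas `floor(size·n_f/N)` with leftover seats by
  largest remainder (ties: larger family, then lexicographic id). A pure
  `"floor"` mode is provided because richness-proportional designs in
  practice often undershoot their targets; both rules are exposed rather
  than asserting one.
* Seeds: every stochastic function takes one master seed and derives
  counter-based child seeds (`child_seed()`), so site i or replicate r is
  reproducible regardless of how many others are run. This is also what
  makes paired designs (Q4, Q5) share null draws between the two methods
  of a pair, removing null-sampling noise from the paired differences.

## Numerical choices

* Rank ties are detected with a 1e-9 relative tolerance. Metric values on
  trees tie exactly surprisingly often (on an ultrametric tree the
  patristic matrix takes few distinct values), and bitwise comparison
  makes ranks unstable under global branch rescaling or algebraically
  equivalent computation routes. With the tolerance, SES, rank-p and
  pattern are invariant to scaling all branch lengths by c > 0 (tested at
  c ∈ {0.01, 1, 100}) and identical between "prune the tree" and
  "restrict the full patristic matrix" (tested to 1e-9).
* Degenerate nulls (zero null sd — community = full pool, star-tree MPD)
  yield `NA` SES and pattern rather than ±∞.
* Zero-length branches are accepted (arbitrarily resolved polytomies
  produce them); negative lengths are rejected. Chronogram-tagged trees
  must be ultrametric within relative tolerance 1e-6, absorbing the
  rounding noise of time-calibration software.
* Ladder rooting (`root_by_ladder()`): when a basal candidate set is only
  partially present in a subset tree, we root on the MRCA of the present
  members. Field pipelines that re-root subset trees on "the most basal
  lineage included" rarely say what they do in this case; the MRCA rule is
  our choice and is documented at the function.
* Wilcoxon signed-rank (normal approximation, two-sided) is the default
  paired test for method comparisons because SES differences need not be
  normal; a paired t-test is available via `test = "t"`. All-zero
  differences are reported as degenerate with p = 1. No multiplicity
  correction is applied across community × size cells by default (matching
  how such studies report per-community results); `adjust_test_table()`
  adds Benjamini–Hochberg when screening many cells.

## What the simulators emulate — and what they do not

`simulate_chronogram()` draws a birth–death (default Yule) tree conditioned
on the tip count, rescaled to unit depth. `derive_phylogram()` multiplies
each branch by an i.i.d. lognormal(0, σ) rate — a deliberately simple
rate-heterogeneity model with no autocorrelation along the tree.
`derive_families()` cuts the chronogram at a depth; families are therefore
perfectly monophyletic, unlike real taxonomies. `simulate_communities()`
assembles sites neutrally, by filtering (weights `exp(−λ·d(focal, i))`,
a smooth kernel that degenerates exactly to neutral at λ = 0), or by
repulsion (greedy max–min selection with softmax temperature 1/λ). The
default 14-site scenario mix uses a fixed right-skewed richness profile
(~2–18% of the pool per site, summing to ≈1 expected occurrence per
species) so that most occurring species are found in exactly one site —
the occupancy skew typical of floristic survey data at a single station.

`perturb_tree()` emulates tree re-estimation error with j random rooted
NNI moves plus lognormal(0, τ) branch noise (defaults j = 5, τ = 0.2).
This stands in for actually re-inferring trees from sequence data, which
is outside this package's scope; it reproduces the *kind* of disagreement
(local topology + branch-length jitter) but not its correlation with
branch support or taxon sampling density.

Consequently, passing tests on synthetic data show that the pipeline
detects the patterns its assembly models induce, at calibrated type-I
error, and that the five experiment designs behave as intended. They do
not show that any particular real community is clustered, nor that real
reconstruction error is as benign as the emulator's.

## Problem sizes

The shipped test-and-reproduction battery uses pools of 60–200 tips,
14 or fewer sites, subset sizes 25–150, 30–50 replicates per size, and
199–999 null replicates — a scale at which a complete run takes a few
minutes on one CPU while leaving the Monte-Carlo error of each reported
proportion at a few percent. Pool size, sizes, replicate and null counts
are all arguments, so paper-scale designs (hundreds of taxa, 100
replicates, 1,000 nulls) are one argument change away.

## Known limitations

* Only the tip-shuffle ("taxa.labels") null is implemented; richness- or
  frequency-preserving swap nulls are out of scope, as are
  abundance-weighted metrics and other phylodiversity families.
* The filtering/repulsion simulators use patristic distance as the niche
  axis; they cannot represent convergent trait filtering.
* `run_q4()`'s emulator perturbs the *pruned* tree; systematic biases of
  real re-estimation (e.g. branch-length shrinkage with sparse sampling)
  are not modelled.
* The experiment runners restrict MPD/MNTD analyses via the full tree's
  distance matrix (equivalent to pruning, and tested as such); PD always
  re-prunes, so very large pools pay a per-replicate pruning cost.
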