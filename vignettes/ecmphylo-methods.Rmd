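---
title: "Methods: community phylogenetics of ectomycorrhizal fungi across soil types"
author: "ecmphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community phylogenetics of ectomycorrhizal fungi across soil types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Serpentine (ultramafic) soils — low Ca/Mg ratio, elevated Ni and Cr, poor
macronutrients — are a classic "extreme" edaphic environment that filters
plant communities strongly. Whether they filter the ectomycorrhizal (ECM)
fungi that partner those plants is much less clear. `ecmphylo` implements a
complete analysis pipeline for asking that question with molecular survey
data: root-tip ITS sequences are delimited into species-level OTUs, a
species-level community phylogeny is assembled hierarchically from two
ribosomal markers, and the phylogenetic structure of each habitat's
community is compared against null models. Diversity (rank/frequency,
accumulation curves, ordination) and soil chemistry (per-parameter ANOVA)
complete the picture.

Two contrasting outcomes frame the analysis. If serpentine soil is an
environmental filter and tolerance is phylogenetically conserved, the
serpentine community should be a *clustered* subset of the regional pool
(positive NRI/NTI, low overlap between habitats). If it is no barrier at
all, both habitats should look like random draws from the pool: equivalent
richness, random phylogenetic structure, overlap near the random
expectation. The synthetic-data generator reproduces exactly these two
worlds so every stage of the pipeline can be validated end to end.

# Pipeline stages

## OTU delimitation

Root-tip ITS sequences are grouped at a conservative 95% global-alignment
identity cut-off. Identity uses Needleman–Wunsch global alignment (match
+1, mismatch −1, linear gap −2) with terminal gap columns excluded from the
denominator — reads differ in length, and overhangs carry no information —
so a 20-mer differing at one site scores exactly 0.95 and merges at the
default threshold. Grouping is *single linkage*: two sequences share an OTU
iff a chain of pairs at ≥ threshold connects them. Single linkage was
chosen because it yields an input-order-independent partition and matches
the inclusive spirit of a "conservative" cut-off; the identity definition
and linkage are both configurable because survey papers rarely state them.
Raising the threshold can only split OTUs (refinement), never merge them —
a property the test suite checks.

Each OTU gets a majority-rule consensus: members are pairwise-aligned to
the cluster seed (the longest member; first on ties) and projected onto the
seed's columns (insertions relative to the seed are dropped — a documented
simplification of progressive alignment). Exact ties take IUPAC ambiguity
codes rather than arbitrary picks, for determinism. Genus assignment
follows the unanimity rule used with BLAST hit lists: a query is assigned
iff its first 20 hits exist and all name one genus; fewer hits, or any
disagreement within the first 20, is a rejection (a value, not an error).

## Chronograms by nonparametric rate smoothing

The genus-level backbone arrives with maximum-likelihood substitution
branch lengths. `nprs_smooth()` converts it to a relative-time chronogram
by minimising Sanderson's nonparametric roughness

$$W = \sum_k \left(r_k - r_{pa(k)}\right)^2 +
      \sum_{c \in \mathrm{children(root)}} \left(r_c - \bar r\right)^2,
\qquad r_k = \frac{b_k}{t_{pa(k)} - t_k},$$

with tip ages fixed at 0 and the root age normalised to 1 (the analysis
uses no fossil calibrations, so only relative time is identified). The
root has no ancestral rate; its children are penalised against their mean
rate — Sanderson's device, stated explicitly here because implementations
differ. Ages are parameterised as nested fractions of the parent age
through a logistic transform with margin $10^{-6}$, which keeps
parent > child smoothly and lets plain BFGS do the work; five jittered,
seeded restarts guard against local optima. Polytomies are allowed (the
penalty simply sums over all children). The objective is invariant to
rescaling all input branch lengths by $c$ up to a factor $c^2$, ages are
unchanged — a property test. On clock-like input the clock solution is
recovered with $W \le 10^{-10}$; on small non-clock trees the optimum is
checked against a $10^4$-point grid-search oracle.

## Supertree assembly by rate-scaled grafting

ITS evolves much faster than LSU, so species-level (ITS) trees and the
genus-level (LSU) backbone live on different substitution scales. For each
genus a scale factor is estimated from branch lengths separating the
ingroup from a common outgroup:
$s_g = P_{\mathrm{lsu}} / P_{\mathrm{its}}$, where $P_{\mathrm{its}}$ is
the mean patristic distance from each ingroup tip to the (first) outgroup
tip in the unsmoothed ITS tree and $P_{\mathrm{lsu}}$ the backbone
distance between the genus and the outgroup genus. The crown fraction
$f_g = s_g D_{\mathrm{its}} / L_{\mathrm{lsu}}$ (mean ingroup root-to-tip
ITS depth over the genus stem length) then places the grafted crown at age
$f_g \cdot a_g$ below the attachment node (age $a_g$) of the smoothed
backbone.

The original description mixes substitution and time scales without
saying how they are reconciled; the reading implemented here — scale
factors computed on unsmoothed trees, applied as crown *fractions* of the
smoothed attachment age — is one of several defensible ones and was chosen
because it keeps the final supertree exactly ultrametric by construction.
When the scaled crown would exceed the available stem time, $f_g$ is
capped at $\beta = 0.9$ with a warning rather than erroring: real marker
rate heterogeneity produces such cases, and a hard failure would make
valid inputs unusable. Single-species genera are relabelled in place.
Grafting then pruning back to one representative per genus recovers the
backbone topology exactly (RF = 0), for any choice of representative —
both are tested.

## Community phylogenetic structure

For each habitat the species list is pooled across soil cubes (the
original two-community comparison; per-cube mode is available) and
compared against null distributions of MPD (mean pairwise patristic
distance) and MNTD (mean nearest-taxon distance), presence/absence
weighted. Indices are sign-flipped standardised effects,

$$\mathrm{NRI} = -\frac{\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null}}
                      {\mathrm{sd}(\mathrm{MPD}_{null})},$$

so clustering is positive. Three null models are provided:

* **independent swap** (the default; "randomization method 3"): Gotelli's
  trial-swap chain flips random 2×2 checkerboards, preserving sample
  richness and species frequency exactly (asserted on every draw). The
  chain is burnt in for 10× the number of matrix cells and thinned by one
  cell-count of trials between samples — defaults stated here because the
  original gives none. Each habitat's species pool is recomputed from each
  randomised matrix.
* **phylogeny shuffle**: tip identities permuted on the tree; a community
  equal to the entire pool is invariant and gets index 0 exactly.
* **pool draw**: equal-richness random subsets of the tree's tips, with
  exhaustive enumeration on demand (population sd is then used; the
  sampled versions use the sample sd — stated because it shifts indices
  slightly).

p-values use $(1 + \#\{null \le obs\})/(n+1)$, one-tailed toward
clustering, ties counted conservatively as ≤; a two-tailed variant is
reported alongside because published index/p pairs rarely state sidedness.
999 runs is the default.

## Diversity and ordination

Rank/frequency curves count, for each species, the number of soil cubes
occupied (ties broken by species id). Sample-based accumulation curves
average cumulative richness over random sample orderings; the mean curve
equals analytic sample-based rarefaction (Mao tau) up to Monte-Carlo error,
which the acceptance suite checks at ±2%. The 95% interval is a percentile
bootstrap over resampled sample sets. A percentile bootstrap of a richness
curve is biased low at deep $k$ (the union of a with-replacement resample
is a subset of the observed pool), which can push the upper percentile
below the mean at $k = n$; the interval is therefore clamped to contain
the mean curve, and this clamp is the only post-processing applied.

Ordination is Kruskal stress-1 NMDS, written here rather than wrapped:
classical-scaling start plus 19 random restarts, isotonic
(pool-adjacent-violators) regression of configuration distances on
dissimilarity ranks (ties in the dissimilarities keep their stable input
order — the "secondary" tie approach), Guttman updates with step halving so
stress is non-increasing within a run, convergence at a stress change
below $10^{-6}$ or 500 iterations. Stress is reported ×100 (percent), the
scale on which survey ordinations conventionally print it. The
dissimilarity is Bray–Curtis on presence/absence (= 1 − Sørensen); low
species frequencies routinely disconnect the sample graph, so samples
outside the largest connected component (dissimilarity < 1 edges) are
discarded first, mirroring the original analysis in which 22 of the
sequenced samples were dropped.

## Soil chemistry

Each soil parameter is compared across habitats with a standard
equal-variance one-way ANOVA, either from raw replicates or directly from
printed mean/sd/n summaries — both paths give identical F by construction
(with two groups $F = t^2$ of the pooled t statistic). No multiple-testing
correction is applied by default, matching per-parameter significance
reporting in field tables; Holm adjustment and a Welch variant (the
reference table's sds are wildly unequal) are available behind flags. A
bundled serpentine/non-serpentine reference profile (23 parameters, 4
composite samples per group) parameterises the generator and provides
summary-input examples. With both sds zero and equal means the statistic
is undefined and reported as p = 1 with a degeneracy flag; with unequal
means F is infinite and p is reported at the smallest positive double to
keep p in (0, 1].

# The synthetic world

`generate_study()` draws, from one seed, the stated study design: a
regional pool of 64 species (pure-birth tree, depth normalised to 1),
2 habitats × 2 forests × 20 soil cubes, and 3–6 root tips per cube
(mean 4), drawn as $3 + \mathrm{Binomial}(3, 1/3)$. Genera are the
lineages crossing age 0.5 — roughly a dozen genera for a 64-species pool,
about the granularity of a field survey. Sequences evolve under HKY85
(matrix-exponential transition probabilities from a 4×4 eigen
decomposition — exact for any branch length; the alternative per-site
Gillespie simulation was not needed) at 0.1 LSU substitutions/site per
unit depth and 3× that for ITS; ~0.1–0.2 LSU and ~0.3–0.6 ITS pairwise
distances are in the range observed between congeneric and confamilial
fungal sequences, and ρ = 3 gives the two-scale problem the grafting
stage exists to solve. Sequence lengths default to 600 (ITS) and 900
(LSU) bases.

Community assembly implements the two hypothesised worlds. `filtered`
draws species with weight $e^{\sigma}$ ($\sigma$ = `filter_strength`,
default 5) for members of a focal clade — chosen as the smallest clade
with at least twice the maximum cube richness, which guarantees feasible
sampling — yielding clustered communities; `random` is the same draw with
zero weights (one code path, so zero strength reproduces the random model
exactly under one seed); `overdispersed` draws sequentially, up-weighting
species far from those already chosen. No effect-size information exists
for real serpentine filtering; σ = 5 is test configuration, strong enough
that power properties are sharp, and is stated once here and not tuned.
Soil tables are normal draws from the reference summaries with negative
concentrations clipped to zero (counted and warned).

What a green test does *not* establish: the generator evolves markers
clock-like on the true tree (no lineage rate variation), simulates no
indels or rate heterogeneity across sites, no sequencing failure (the
original survey lost ~35% of root tips), no chimeras, and no
within-species ITS variation — so OTU delimitation on synthetic data is
easier than on real reads, and the supertree stage sees cleaner scale
factors than GenBank congeners would give. Green means the machinery is
correct, not that field data would behave this well.

# Numerical choices

* NPRS: BFGS, relative tolerance $10^{-14}$ on the objective, age margin
  $10^{-6}$ in the nested-fraction transform, 5 seeded restarts (jitter
  sd 0.5 on the logit scale).
* Grafting: crown cap β = 0.9; ultrametricity asserted at $10^{-8}$
  absolute deviation on unit-depth trees.
* NMDS: 20 restarts, 500 iteration cap, stress change tolerance
  $10^{-6}$, step halving up to 20 times per iteration; "converged" means
  the best two restarts agree within 1% relative stress.
* Null models: 999 runs, burn-in 10 × cells, thinning 1 × cells; sample
  sd for sampled nulls, population sd for exhaustive enumeration;
  degenerate nulls (sd = 0) yield index 0 when the observation equals the
  null mean.
* Determinism: every stochastic stage draws from the single stream seeded
  by the run configuration; standalone calls accept their own seed and
  restore the caller's RNG state afterwards. Pipeline outputs are written
  with fixed `%.12g` formatting so reruns are byte-identical.

# Known limitations

* The grafting formula is one reading of an under-specified procedure
  (the original scaling/grafting script was never published); a
  scale-then-smooth alternative is noted but not implemented.
* Pooled-habitat communities under the independent-swap null change their
  richness between null draws (frequencies are conserved, membership is
  not), so NTI for a small clustered community can sit below zero even
  when the community is genuinely clustered — a known artifact of pooled
  analysis, visible in the synthetic demonstrations.
* More generally, MNTD-based tests have little power when a pooled
  community covers a large fraction of the pool: a random half of a tree
  already has small nearest-neighbour distances. In the strong-filtering
  demonstration (pool 32, ~15 pooled species) NRI rejects in ~98% of
  replicates but NTI in only ~50%, and NTI is positive in ~92% rather
  than ~99% — the per-cube analysis mode is the right tool when
  nearest-taxon structure is the question.
* The accumulation-interval clamp (above) trades exact percentile coverage
  for the lower ≤ mean ≤ upper invariant.
* Printed soil summaries with rounded sds (e.g. "±0.0") cannot reproduce a
  published significance-star pattern exactly; the suite deliberately does
  not assert one.
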