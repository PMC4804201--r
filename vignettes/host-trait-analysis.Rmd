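---
title: "Host-trait analysis of atmospheric bromeliad assemblages: models and methods"
author: "epihost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-trait analysis of atmospheric bromeliad assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Atmospheric bromeliads (mostly *Tillandsia* species) absorb water and
nutrients from aerosols through leaf scales, and can in principle settle on
almost any substrate — yet in the field their abundance varies by orders of
magnitude between neighbouring trees. `epihost` implements a complete
analysis chain for asking *why*: which functional traits of the host tree
(deciduousness, bark type, peeling, light guild, thorns, needles, trunk
diameter, height, canopy leaf area index) drive (i) how many bromeliads a
tree carries and (ii) where in the crown they sit.

Two per-tree statistics anchor everything:

* `AB_abund` — the total count of bromeliad individuals on a tree
  (hosts and non-hosts alike);
* `AB_dst = A_trunk / A_total` — the trunk share of a host's bromeliads:
  1 means every individual is on the trunk, 0 all on branches, 0.5 a
  balanced crown. It is undefined for non-hosts and those are excluded from
  every distribution analysis.

# Data model

A dataset is three files: a tree-individual table (`trees.csv`, one row per
censused tree with its patch, plot, species, DBH, height, plot LAI and one
`<epiphyte>_trunk`/`<epiphyte>_branch` count pair per bromeliad species), a
species-by-trait table (`traits.csv`) and a host-species phylogeny with
branch lengths (Newick). `read_dataset()` cross-validates them — every
species in the census must appear in both the trait table and the
phylogeny, counts must be non-negative integers, tree ids unique — and
computes the derived fields. Two choices are deliberate:

* **Trait kinds are declared, never inferred.** A YAML sidecar (or the
  built-in `default_trait_kinds()`) says which traits are categorical,
  binary or quantitative. Silently treating bark type as a number would
  corrupt the trait tree without any error surfacing.
* **Categorical levels keep first-appearance order** from the trait file,
  so dummy coding and split-child ordering are deterministic across runs.
* **Missing quantitative trait values are an error**, not imputed; the
  workflows this package supports have none.

# Diversity and co-occurrence metrics

*Faith's PD* is the total branch length of the minimal rooted subtree
spanning a species set, root included, so a singleton's PD is its
root-to-tip path length. The include-root convention keeps single-host
samples well defined and matches the common default of the community
phylogenetics toolchain.

*Functional diversity* (FD) is the same spanning-length construction on a
functional dendrogram: Gower dissimilarity over the declared mixed traits
(equal weights, quantitative traits range-normalised over the species pool,
simple matching for categorical and binary; a constant quantitative trait
contributes zero) followed by UPGMA agglomeration. UPGMA ties are broken by
merging the pair whose representative leaf labels sort first — ties are
measure-zero with continuous traits but the rule pins exact reproducibility
for discrete ones.

*Phylogenetic species structure.* The correlation matrix `C` is the shared
root-to-tip branch length divided by the maximum tip depth (equivalent to
extending terminal branches until the tree is ultrametric), with unit
diagonal; megatree-derived phylogenies are not guaranteed ultrametric and
the correlation interpretation requires a common depth. On the species
present in a community row:

* `PSV = (n^2 - sum(C)) / (n (n - 1))` — 1 on a star phylogeny
  (maximal variability), shrinking as relatives co-occur;
* `PSR = n * PSV` — richness discounted by relatedness;
* `PSE` — the abundance-weighted form: each individual is a unit,
  conspecific individuals are perfectly correlated, and the denominator
  counts only heterospecific pairs, `PSE = (M^2 - a'Ca) / (M^2 - M * mean(a))`
  for abundance vector `a` with total `M`. This is the form that collapses
  to PSV at equal abundances; a naive "PSV of the expanded matrix with
  denominator M(M-1)" does not, and is therefore not used.
* `PSC = 1 - mean_i max_{j != i} C_ij` — clustering of each species to its
  closest present relative.

*Schoener's co-occurrence index* for species i and j over samples k is
`S_ij = 1 - 0.5 * sum_k |p_ik - p_jk|` with `p_ik` species i's relative
abundance in sample k: 1 for identical relative use, 0 for disjoint use,
invariant to rescaling any one species. Its correlation with patristic
distance over the species pairs is the test statistic for phylogenetic
structure in host use.

# Null models

All three randomization procedures return `null_envelope` objects: the
observed value, the null draws, the empirical 2.5%/97.5% quantiles and a
verdict (`below` / `within` / `above`). Quantiles use the type-7
(linear-interpolation) estimator so envelope fixtures are exactly
reproducible; every procedure conserves total abundance by construction,
and every function takes a seed.

1. **Individual randomization** (`randomize_individuals_null`): each
   replicate re-assigns every bromeliad individual of a patch independently
   and uniformly to one of the patch's trees, then records host-species
   richness, PD and FD of the occupied species. Uniform-per-tree is the
   minimal reading of "random placement on the patch's trees"; weighting by
   tree size is exposed via `weights` but off by default. The default
   10 000 replicates match the convention for this analysis; tests use
   1 000.
2. **Tip shuffling** (`tip_shuffle_test`): permutes phylogeny tip labels
   (1 000 runs by default) and recomputes the co-occurrence/distance
   correlation; the community matrix — hence the Schoener matrix — never
   changes, so the null isolates the phylogeny's contribution.
3. **Frequency-preserving abundance shuffle** (`psd_null_test` via
   `frequency_preserving_shuffle`): permutes each species' abundances
   across samples independently, preserving exactly each species' total and
   occurrence frequency, then recomputes PSV/PSR/PSE/PSC on pooled group
   rows. Verdicts are labelled `Clustered` (below), `Random` (within),
   `Overdispersed` (above). One subtlety drove the interface: if the
   pooling group spans *all* samples, the pooled row is invariant under
   within-column permutation and every envelope degenerates at the observed
   value. The test is therefore run on a plot-by-species matrix with one
   pooling group per vegetation patch, which lets abundance move between
   patches while holding the species pool fixed.

**Calibration.** Under data generated by the null's own mechanism the
observed statistic should leave the 95% envelope about 5% of the time.
For a discrete statistic like richness the inclusive envelope over-covers;
the calibration experiment in the acceptance suite therefore uses 30 trees
of 30 species with 30 individuals — sized (before any acceptance run) so
the richness null has a wide support and coverage stays near nominal — and
checks coverage against a binomial 99% band around 95%.

# Hierarchical partitioning

`goodness_of_fit()` returns R² for gaussian responses and deviance
explained `1 - D(model)/D(null)` for Poisson counts and binomial
(trunk, branch) proportions; the empty predictor set returns 0, and a
perfect non-gaussian fit warns about separation and reports 1. Categorical
predictors enter and leave as whole dummy blocks — one trait is one
explanatory unit.

`hier_part()` decomposes the full-model fit over predictors: the
independent contribution of predictor x is its average fit increment over
all k! predictor orderings, computed by level-weighted averaging over the
`2^(k-1)` subsets not containing x with weights `|S|! (k-1-|S|)! / k!`.
The contributions always sum to the full-model fit (asserted to 1e-8 in
the tests, against brute-force enumeration of all orderings for k ≤ 4),
and the joint contribution is `J = R({x}) - I`. Fits run in a small
compiled IRLS engine because a randomization test multiplies `2^k` subset
fits by the number of permutations; k is capped at 12.

The significance test permutes the response `n_rand` times (1 000 by
default, 199 in the scaled-down test runs) and recomputes every I. Each
predictor gets the conventional randomization z-score
`z = (I_obs - mean(I_null)) / sd(I_null)` *and* an exact one-tailed
permutation p-value `(1 + #\{I_null >= I_obs\}) / (n_rand + 1)`;
significance is flagged from the exact p-value at the nominal 0.05 level.
This is a deliberate departure from the historical convention of flagging
`z >= 1.65`: the permutation null of I is right-skewed
(chi-square-like), so the normal-approximation cutoff has a true
per-predictor size of roughly 8–11% rather than 5% (measured during
development; the same inflation has been reported for the convention in
the literature). The exact criterion tests at the same nominal level and
is calibrated by construction; z is still reported so results remain
comparable with analyses that print z. Even so, when several candidate
predictors are tested at one node, the chance that *some* predictor comes
out significant on pure noise is roughly `k` times 5%, less a correction
for the correlation induced by sharing one permutation set — worth
remembering when reading deep trait trees (below).

# The trait tree

`trait_tree()` implements the successive-hierarchic-partition algorithm.
At each node it runs the partitioning randomization test on the remaining
candidate predictors; if none is significant the node is a leaf; otherwise
it splits on the predictor with the largest z — one child per observed
level for categorical traits, a two-way split at the *node* median for
quantitative ones (values equal to the median go to the lower side; a
pinned convention is required for determinism) — removes that predictor
from all descendants, and recurses. Nodes smaller than `min_node`
(default 10 — the stopping is primarily significance-driven, `min_node`
backstops GLM degrees of freedom) or with constant response become leaves.
The abundance tree uses all trees with Poisson GLMs; the distribution tree
uses hosts only with binomial GLMs on (trunk, branch) counts. Node medians
(not whole-dataset medians) are used for quantitative splits because each
partition is re-run inside the subgroup.

Leaf means feed `assign_patterns()`: a tree individual is a *best host*
if its abundance-leaf mean exceeds 400 individuals, *worst* below 10,
*trunk host* if its distribution-leaf mean exceeds 0.9, *branches host*
below 0.1; intermediate leaves carry no label, and non-hosts get
`trunk = branches = FALSE` so the all-trees pattern matrix downstream is
complete. `pattern_overlap_counts()` tabulates species by the exact
combination of patterns their individuals reach — the counts behind an
Euler diagram of pattern overlap.

# Association statistics

`patch_comparison()` fits the patch-factor GLM (Poisson for abundance over
all trees, binomial for the trunk share over hosts), reports the
likelihood-ratio chi-square, and runs all pairwise patch contrasts with
**Holm** adjustment summarised as a compact letter display. Holm-adjusted
likelihood-ratio contrasts replace single-step Tukey comparisons on GLMs:
Tukey's multivariate-t machinery is toolchain-specific for non-gaussian
models, while Holm is exact-level and reproducible — a deliberate,
documented deviation. Poisson models are used without overdispersion
correction, matching the chi-square reporting convention of this analysis
family; binomial responses weight hosts by abundance through their
(trunk, branch) totals.

`diversity_regressions()` fits per-predictor ordinary least squares of
plot-level abundance or trunk share on host richness, PD and FD, with
ANOVA F tests. `pattern_pca()` is a centered covariance PCA (columns not
scaled to unit variance — the loading magnitudes this analysis family
prints are inconsistent with a correlation PCA) of the trees-by-four 0/1
assignment matrix, sign-fixed so the best-host loading is negative;
`score_glm()` relates PC1 scores back to abundance (Poisson) or trunk
share (binomial). `assignment_crosstab_tests()` is the 2x2
likelihood-ratio chi-square between pattern assignments, with the
direction (likely/unlikely) read off the slope sign and degenerate margins
reported as untestable rather than thrown.

# Synthetic data

`named_scenarios()` ships five generating configurations; all share the
sampling design of five vegetation patches x five 10 m x 10 m plots, a
species pool with trait syndromes, Poisson abundance rules keyed on trait
predicates, trunk-allocation probabilities, and a strongly skewed
four-species epiphyte mix (0.94/0.03/0.02/0.01 — one hyper-dominant
species, as such assemblages typically show). Abundance and allocation are
conditionally independent given traits, mirroring the separate abundance
and distribution analyses.

* `null` — no trait effect (mean 5 everywhere, allocation 0.5): the
  stochastic-assembly baseline; a grown trait tree should usually stop at
  the root.
* `deciduousness_only` — mean 400 on deciduous trees vs 3 elsewhere over
  a varied eight-species pool.
* `two_stage` — the nested rule a recursive partition should recover:
  deciduous trees with DBH ≤ 150 cm have mean 400, everything else mean 3;
  400 trees, about 200 per deciduousness arm. The pool is designed for
  identifiability of its own generating rule: the two deciduous species
  share the DBH range (50, 250) so the generating threshold *is* the
  median of the deciduous stratum (the generating rule is itself a median
  split); evergreen DBH, height, LAI and all remaining traits are held
  constant so no variable is marginally confounded with the rule variables
  and no nuisance candidate is available to produce spurious splits below
  the true ones (with per-node multiple testing, a handful of varying
  nuisance traits at each of three downstream nodes would put spurious
  splits in a sizeable fraction of runs).
  With overlapping evergreen DBH or freely varying nuisance traits the
  marginal signal of DBH rivals that of deciduousness and recovery of the
  generating topology drops to roughly a coin flip; that configuration
  tests the method's limits, not its correctness, and is not what this
  scenario is for.
* `tp_like` — a silviculture-grove-like configuration: the hyperabundant
  small-DBH deciduous stratum sits on a reticulated-bark species whose
  trunk-attachment probability is 0.04, pushing >70% of individuals onto
  branches.
* `mixed_forest` — a diverse pool with modest trait effects and
  bark-driven allocation, standing in for secondary/reforested patches.

What the generator does **not** emulate: spatial autocorrelation within
and between plots, dispersal limitation, neighbour shading interactions,
overdispersed (non-Poisson) counts, and within-species trait variation
beyond DBH/height draws. Tests passing on these scenarios therefore
demonstrate that the *algorithms* behave as specified under the assumed
statistical structure, not that real censuses satisfy that structure.

# Problem sizes and numerical choices

The test and acceptance runs use scaled-down sizes chosen as a matter of
experimental design: 199 permutations per node test and 20 seeds for
structure recovery; 1 000 replicates per null envelope with 200
repetitions for calibration; 10 000-replicate defaults remain on the
user-facing functions. Envelope quantiles are type-7; UPGMA ties are
lexicographic; median ties go left; IRLS runs to a 1e-9 relative deviance
tolerance with eta clamped to ±30 (a perfectly separated binomial fit
reports deviance explained 1 rather than diverging); goodness of fit is
clamped to [0, 1] against rounding.

# Limitations

* The node test is exact per predictor, but testing several candidates at
  every node means deep trees grown with many candidate traits will still
  contain occasional noise splits, and strongly confounded designs can
  mask the intended split variable. The randomization seed, permutation
  count and candidate set are therefore always recorded with the tree.
* Hierarchical partitioning is exponential in the number of predictors
  (capped at 12 whole-trait blocks).
* Plain Poisson GLMs will overstate significance on overdispersed counts;
  real bromeliad counts are often overdispersed, and patch chi-squares of
  the magnitude this analysis family reports should be read as ordering
  evidence, not exact tail probabilities.
* The PCA of pattern assignments treats 0/1 indicators as numeric — a
  pragmatic ordination, not a latent-variable model.
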