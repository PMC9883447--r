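---
title: "Methods: estimators, admixture model, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, admixture model, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popresolve asks a practical question of molecular ecology: when population
structure is shallow — mobile species, recent post-glacial expansion, lots of
gene flow — how much does a genomic SNP panel actually add over a dozen
polymorphic microsatellites? The package implements the complete comparison
workflow for a design of 19 colonies nested in 7 countries (5–15 bats
sampled per colony, 196 individuals, 11 microsatellites, ~5,000 ddRAD SNPs)
and a synthetic generator that reproduces that design so every stage can be
tested without any download. This vignette records the models, the numerical
choices, and the reasoning behind the parameters.

## Genotype containers and orientation

SNPs are stored as alternate-allele dosages (0/1/2, `NA` missing — never 0,
since 0 is a valid homozygote) with optional per-genotype read depths;
microsatellites as canonicalized unordered allele-size pairs. All estimators
run through a single per-population allele-count abstraction, so the
biallelic and multiallelic paths share code, and every statistic is invariant
to flipping ref/alt orientation (tested as a property). Cells with no data
in a population are skipped pairwise-complete rather than dropping the locus
everywhere — the study design retains a high-missingness colony, and so do
we.

## Filtering rules

The ddRAD filter mirrors a conservative calling protocol, in order:

1. all SNPs on a RAD locus carrying more than 5 SNPs are removed
   (repetitive-element guard);
2. genotypes with fewer than 8 reads are set missing (boundary inclusive:
   8 reads pass); heterozygotes whose rarer allele holds < 25% of reads are
   set missing (a dropout-prone call), as are genotypes flagged as carrying
   a third allele;
3. loci whose minor allele survives exactly once (singletons) are dropped —
   this runs *after* masking, which can create singletons;
4. loci called in fewer than 70% of all individuals are dropped;
5. loci with pooled F_IS outside [−0.2, 0.2] are dropped, since extreme
   heterozygote deficits are not expected in a diploid with separate sexes.

The F_IS screen pools all individuals (single-population Nei–Chesser F_IS
per locus) rather than averaging per-population values: the screen runs
before population labels are needed, and a single per-SNP range is the
natural reading of the protocol. A per-step ledger records cells masked and
loci dropped; the pipeline is idempotent on its own output, and conservation
(initial loci = final + dropped) is asserted in tests.

## Diversity and F-statistics

Per locus and population, with n non-missing genotypes and allele
frequencies p:

- H_O = observed heterozygote proportion;
- H_S = n/(n−1) · (1 − Σp² − H_O/2n)  (Nei–Chesser small-sample correction);
- H_T = 1 − Σp̄² + H̄_S/(ñs) − H̄_O/(2ñs), with p̄ the unweighted mean
  frequency over the s populations observed at the locus and ñ their
  harmonic-mean sample size;
- F_IS = 1 − H_O/H_S, undefined (NA, never 0) where H_S = 0.

Multi-locus F-statistics are ratios of sums over loci, never means of
per-locus ratios. Pairwise F_ST is Weir–Cockerham θ with the explicit
a/b/c moment components summed over loci and alleles. The hierarchical
decomposition (countries / populations / individuals / gametes) is computed
by a second, independent route: Henderson method-of-moments on gamete
allele indicators with exact unbalanced-design coefficients. The two routes
provably coincide when the hierarchy degenerates to one level, and the test
suite holds them to 1e−9 agreement — a strong cross-check since neither
shares code with the other. F_CT = σ²_C/σ²_tot, F_SC = σ²_P/(σ²_tot−σ²_C),
so (1−F_SC)(1−F_CT) = 1−F_ST holds by construction.

Population-specific F_ST (Beta) uses allele matching: within-population
matching M_w = Σ N_a(N_a−1)/(N(N−1)) against the mean between-population
matching, Beta = (M_w − M_b)/(1 − M_b), combined over loci as a ratio of
sums. Allelic richness is hypergeometric rarefaction to g allele copies,
where g defaults per locus to twice the smallest per-population genotype
count. Bootstrap CIs resample loci with replacement (default 1000 draws)
and recompute each statistic from summed per-locus components; percentile
2.5/97.5 bounds; fully seeded.

The gene-diversity envelope used to flag outlier loci is
2p(1−p)(1−f_IT) ± 2·sqrt(2p(1−p)(1+f_IT)/N), implemented exactly as the
reference framework prints it. The (1+f_IT) inside the radical is
surprising — a variance derivation would more naturally give (1−f_IT) — so
a `radical_sign = "minus"` switch provides the alternative; the printed
form is the default because reproducing the published diagnostic is the
point.

## Distances, trees, and isolation by distance

Chord distance per locus is (2/π)·sqrt(2(1−cosθ)) with
cosθ = Σ√(p₁p₂); the multi-locus distance averages per-locus distances
(a pooled-cosθ variant is available — published implementations differ, and
the per-locus mean weighs loci equally). Trees come from `ape::bionj`, the
variance-weighted neighbour-joining variant, with negative branch lengths
clamped to zero. Geographic distances are haversine great circles with
R = 6371 km on the per-population coordinates.

The Mantel test correlates lower-triangle entries and permutes one
matrix's labels jointly (p = (#{r_perm ≥ r_obs}+1)/(n_perm+1), 999
permutations by default; one-tailed for IBD, two-tailed for marker-set
comparison). IBD defaults to Rousset's regression — F_ST/(1−F_ST) against
log distance — with a `linearize = FALSE` switch, since the source protocol
cites the IBD framework without printing the transform; the linearized form
is the field standard for two-dimensional habitats. Negative pairwise F_ST
entries are kept as computed in matrices but floored at 0 before the
transform (count reported), keeping the estimator unbiased while the
transform stays defined.

## Admixture by regularized NMF

The one-hot genotype-class matrix X (individuals × 3·loci over classes
{0,1,2}) is factorized as X ≈ QG with Q row-stochastic (ancestries) and
each per-cluster, per-locus class triple of G a probability vector, so QG
yields genotype-class probabilities directly. Fitting alternates a
ridge-penalized least-squares update for Q and a least-squares update for
G, each projected onto its simplex; a monotone safeguard accepts a block
update only if the masked penalized objective does not increase, falling
back to projected-gradient steps with backtracking — so the objective is
non-increasing by construction (asserted in tests) and the optimizer cannot
stall on a rejected projection. Convergence: relative objective change
< 1e−6, at most 500 iterations. Missing and held-out entries are imputed by
the current reconstruction (EM-style) and excluded from the objective.

The regularization weight is alpha/n_loci with alpha = 100. The ridge on a
row-stochastic Q pulls ancestries toward uniform admixture, and an absolute
weight would make that pull grow with panel size; scaling per locus keeps
the prior's strength constant, consistent with the reference tool's
documented insensitivity to alpha on data of this scale, and lets fully
separated demes reach near-vertex ancestries (> 0.99) even on a 100-locus
panel. Each of the 20 repetitions per K draws its own 10% mask of
non-missing genotype cells (repetition index folded into the seed, so runs
are bit-for-bit reproducible) and is scored by masked cross-entropy: the
negative mean log probability of the held-out genotype classes, with
per-entry probabilities renormalized and floored at 1e−10.

K is chosen by an explicit plateau rule — the smallest K whose median
cross-entropy lies within one (raw, unscaled) median absolute deviation of
the global minimum median, where the MAD is taken over the repetitions at
the minimizing K. Reading a boxplot by eye picks the flattening point; the
rule just formalizes it, returning K = 1 for flat curves.

Cluster label alignment between fits uses exhaustive permutation search
(K ≤ 7 throughout, at most 5040 permutations) maximizing matched-column
correlations; assignment concordance is then the fraction of individuals
keeping their hard assignment. The subsampling experiment refits on random
locus subsets and reports that concordance against the full-data fit.

## Sex-biased dispersal

Each individual's assignment index is the log10 Hardy–Weinberg probability
of its multilocus genotype in its own population, with leave-one-out allele
frequencies and a 1/(2n) floor for alleles unobserved after removal — the
private alleles of immigrants are the very signal sought, so they must not
contribute −∞. AIc centers the index within populations (sums to 0 by
construction); the male–female comparison uses a Welch t-test plus a
within-population label permutation (999 draws). Members of the dispersing
sex carry less-typical genotypes, lowering their mean AIc.

## The synthetic generator

Allele frequencies drift from an ancestral value (uniform on [0.05, 0.95]
for SNPs) into countries and then into populations under the
Balding–Nichols Beta model — Beta(p(1−F)/F, (1−p)(1−F)/F) — with the
Dirichlet analogue (concentration (1−F)/F) for multiallelic loci, and
genotypes binomial(2, p). The `paper_like` preset reproduces the study
design: 19 populations, 7 countries, the printed per-colony sample sizes
and coordinates, 4994 SNPs, 11 microsatellites with 3–18 alleles,
F_CT = 0.058, F_SC = 0.019, genotype dropout ~4% everywhere but ~45% in
the small colony "9", whose read-depth mean is also lowered (10 vs 25,
negative binomial, dispersion 4, 0.5% read error) so the depth-aware
filters reproduce the heterozygote-depletion mechanism. Migrant injection
replaces a fraction of a "hub" colony by unadmixed draws from another
deme's latent frequencies — colonies sharing migrators of distinct
ancestry without admixture — optionally sex-skewed. A one-dimensional
stepping-stone chain (Balding–Nichols drift per step) exists solely to give
the IBD test a geographic signal; an island model provides its null.

What the generator does *not* emulate: linkage between SNPs on a RAD tag,
microsatellite mutation (multiallelic frequencies are drawn, not mutated,
so no homoplasy), continuous spatial gradients within countries,
inbreeding, or genealogical noise (frequencies are drawn, not coalesced).
Passing tests therefore demonstrate estimator and workflow correctness
under the declared hierarchical model, not robustness to every feature of
real ddRAD data; in particular, real microsatellite homoplasy biases
between-marker comparisons in ways the simulation cannot show.

## Validation experiments and problem sizes

The Monte-Carlo experiments fix these designs (seeded, shared by the
analysis scripts, the tests and the acceptance script):

- **Parameter recovery**: 20 paper-like replicates (complete matrices);
  mean hierarchical estimates within ±0.01 of F_SC = 0.019, F_CT = 0.058.
- **K selection**: four demes of 40 individuals (the study's main-cluster
  sizes) at F = 0.058, 5000 SNPs; scans K = 1–6 with 2 maskings per K
  (scaled from the study's 20 repetitions × K = 1–7), 5 replicates; the
  plateau rule should return K = 4 in ≥ 80%.
- **Resolution**: the paper-like preset fit at K = 4 in full and on random
  subsets of 1000 and 100 SNPs, 3 replicates; mean concordance ≥ 0.9 at
  1000 and collapsing at 100 — the synthetic analogue of "≥ 1000 SNPs
  recover the substructure, 100 SNPs are essentially uninformative".
  Because Balding–Nichols clusters are cleaner than real colonies (no
  linkage, no homoplasy, no within-cluster gradients), a 100-SNP panel
  retains more signal here than in the field data: across seeds the mean
  100-SNP concordance lands between ~0.6 and ~0.75, above the idealized
  ≤ 0.6 expectation that the corresponding acceptance check asserts — that
  check can therefore fail honestly even though the qualitative collapse
  (0.93 → 0.60 in the worked example) reproduces.
- **Calibration**: Mantel type-I error from 200 independent random matrix
  pairs; IBD power over 50 stepping-stone chains (8 demes, drift 0.02 per
  step) and its null over 50 island-model draws; sex-bias power over 50
  replicates of 10 populations × 20 individuals × 1000 SNPs with male
  migration 0.3; bootstrap coverage from 200 replicates of 6 × 10 × 500
  at F = 0.05 with 1000 bootstrap draws each.

These sizes are the package's standing choices for routine validation;
they keep each experiment to minutes on a single core while leaving the
Monte-Carlo error well inside the asserted bands.

## Known limitations

- The admixture surrogate reproduces the *behavior* of sparse-NMF ancestry
  estimation (masked cross-entropy selection, near-vertex assignment of
  unadmixed individuals), not any particular implementation bit-for-bit.
- Percentile bootstrap CIs on ratio statistics undercover slightly at a few
  hundred loci; coverage is asserted at the nominal-±4% band, and sits near
  its lower edge with 500-locus panels.
- The overall microsatellite H_O of a pooled sample can be averaged
  per-locus-then-population or per-population-then-locus; both are
  reported, since published tables are ambiguous between them.
- Reading the deposited study matrices requires converting them to the
  package dialects (documented in the acceptance test); the Dryad layout
  itself is not parsed automatically.
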