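# popresolve

Population-structure inference when there is little structure to find:
a complete R workflow for comparing microsatellite panels against ddRAD-seq
SNPs in weakly differentiated, highly mobile species. The motivating setting
is a continental survey of a migratory bat — 196 individuals from 19
colonies in 7 European countries, genotyped at 11 microsatellites and ~5,000
SNPs — where range-wide differentiation is shallow (F_ST ≈ 0.05–0.07) and
the question is which marker set can still resolve it.

## What it computes

**Filtering.** Depth-aware SNP cleaning with an auditable ledger: ≤ 5 SNPs
per RAD locus, ≥ 8 reads per genotype, ≥ 25% minor-read fraction for
heterozygotes, singleton removal, ≥ 70% call rate, per-locus F_IS within
[−0.2, 0.2].

**Diversity and differentiation.** Nei–Chesser H_O, H_S (gene diversity),
h_T, F_IS with locus-bootstrap CIs; rarefied allelic richness
A_R = Σᵢ[1 − C(N−Nᵢ, g)/C(N, g)]; population-specific F_ST (Beta) from
allele matching, Beta = (M_w − M_b)/(1 − M_b); pairwise Weir–Cockerham θ as
ratios of summed a/b/c variance components; hierarchical F_SC/F_CT
(populations within countries) from an exact unbalanced nested
method-of-moments decomposition of gamete allele indicators; the
gene-diversity envelope 2p(1−p)(1−f_IT) ± 2·sqrt(2p(1−p)(1+f_IT)/N) for
outlier screening.

**Geography.** Chord distances, (2/π)·sqrt(2(1−Σ√(p₁p₂))), BIONJ trees,
haversine distances (R = 6371 km), seeded Mantel permutation tests, and
Rousset-linearized isolation by distance.

**Individuals.** Genotype PCA (microsatellites expanded to per-allele
indicator dosages); admixture by regularized nonnegative matrix
factorization of one-hot genotype classes, X ≈ QG with row-stochastic Q,
masked cross-entropy on 10% held-out genotypes, plateau-rule K selection;
a SNP-subsampling resolution experiment (3000 → 100 loci); and a corrected
assignment-index (mAIc) test for sex-biased dispersal.

**Simulation.** A hierarchical Balding–Nichols generator producing matched
SNP + microsatellite datasets under the study design (the `paper_like`
preset), with negative-binomial read depths, colony-concentrated
missingness, unadmixed "hub" migrants, and optional sex-biased dispersal —
so the entire workflow is testable offline.

## Worked example

The numbered drivers under `analysis/` run the full study on synthetic data
(seed 42). `analysis/01_simulate_study.R` generates the design and
`analysis/02_filter_snps.R` applies the cleaning protocol:

```
                                      step cells_masked loci_dropped loci_remaining
 snp_count_per_rad_locus (skipped: no map)            0            0           4994
                                depth_mask        53899            0           4994
                   triallelic_balance_mask         7544            0           4994
                         singleton_removal            0            0           4994
                                 call_rate            0            0           4994
                               fis_outlier            0          410           4584
retained 4584 of 4994 loci; 11.4% missing genotypes after filtering
```

The depth rule masks the low-coverage colony's genotypes (53,899 cells) and
the balance rule removes dropout-prone heterozygote calls (7,544 cells);
the F_IS screen then discards 410 loci with outlying heterozygote deficits.
`analysis/04_differentiation.R` prints the differentiation summary:

```
mean pairwise F_ST: SNP 0.065, microsatellite 0.079
marker-set Mantel: r = 0.66, p = 0.002
IBD (snp): Mantel r = 0.83, p = 0.001, slope = 0.01607
hierarchical (snp): Fsc = 0.018, Fct = 0.054
```

The generator was run at F_SC = 0.019 and F_CT = 0.058: the hierarchical
estimates land on the truth, the two marker sets' F_ST matrices correlate,
and isolation by distance emerges from the country-level structure plus the
real sampling coordinates. `analysis/05_individual_structure.R` runs the
admixture scans — the plateau rule picks K* = 4 on the full data and again
on the ≥ 70%-completeness subset (n = 191) — and the subsampling
experiment:

```
 size concordance        # agreement with the full-data ancestry
 3000        0.93
 2000        0.92
 1000        0.93
  500        0.90
  200        0.84
  100        0.60
```

Structure is held down to ~500–1000 SNPs, blurs at 200 and collapses at
100 — while the sex-bias test stays flat for both markers (SNP t = 0.20,
p = 0.84; microsatellite t = −0.63, p = 0.53), and the missingness screen
shows H_O (r = −0.86) and F_IS (r = +0.84) tracking the per-colony missing
fraction with H_S more robust (r = −0.61).
`analysis/06_marker_comparison.R` writes the machine-readable comparison
report (`results/comparison_report.json`), and `analysis/07_calibration.R`
reruns the Monte-Carlo validation suite (parameter recovery, K-selection
reliability, test calibration, bootstrap coverage).

A minimal interactive session:

```r
library(popresolve)
ds <- simulate_dataset(paper_like_config(), seed = 42)
h  <- hierarchical_fstats(ds$snp, ds$meta)
h$fstats
#        Fst        Fsc        Fct
# 0.07082...  0.018...   0.053...  (truth: Fsc 0.019, Fct 0.058)
```

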