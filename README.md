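# strpopgen

Population-genetic analysis of forensic STR (microsatellite) datasets.

Forensic genetics has typed a small panel of autosomal STRs — the 13
CODIS core loci — in hundreds of population samples worldwide, published
either as allele-frequency tables or as individual genotype profiles.
`strpopgen` implements the statistical toolkit needed to mine such data
for signals of human population structure, in both data modes, together
with synthetic-data generators that make every stage testable without
access to the original databases.

## What it computes

**Within-population diversity.** For a sample of *n* gene copies with
allele frequencies *p&#7522;*: unbiased expected heterozygosity
*He = n/(n−1) · (1 − Σ p&#7522;²)* and the variance in repeat number
*Vp* (sample variance of repeat values over copies). Group summaries
with Kruskal–Wallis and Bonferroni-corrected pairwise Wilcoxon tests,
and a Monte-Carlo exact Hardy–Weinberg test (Levene conditional
probability statistic).

**Geography.** Great-circle distances routed through obligatory
migration-gateway waypoints (Anadyr, Cairo, Istanbul, Phnom Penh,
Prince Rupert): a North American sample reaches an East African origin
as population → Anadyr → Cairo → origin. OLS regression of diversity on
distance from the origin, with R² and the slope *t*-test.

**Differentiation.** Two- and three-level AMOVA on allele copies under
the stepwise model (distance = squared repeat difference, giving
*R<sub>ST</sub>*, *R<sub>SC</sub>*, *R<sub>CT</sub>*) or the identity
model (*F* analogues), from genotypes or from frequencies alone
(integer copy counts are reconstructed by largest-remainder rounding).
Multi-locus indices sum variance components over loci; significance
comes from scheme-appropriate permutation tests and Fisher's combined
probability across loci. Pairwise index matrices feed Reynolds
coancestry distances *D = −ln(1 − θ)*, nonmetric MDS (Kruskal stress-1)
and a one-tailed Mantel test against routed geographic distances.

**Ascertainment.** Locus panels ranked by mean He across population
samples (top-*k* / bottom-*k* / random), compared on mean He,
across-population variance of He and multi-locus index — quantifying how
choosing maximally discriminating markers compresses apparent population
structure. Levene variance tests (mean or median centering) included.

**Synthetic data.** A forward-time Wright–Fisher serial-founder
expansion (single-step mutation, sequential deme foundings along a
line) producing the out-of-Africa-style diversity gradient, and a
Balding–Nichols frequency generator with known differentiation *F* for
parameter-recovery checks.

## Worked example

```r
library(strpopgen)

sim <- simulate_serial_founder(sim_params(seed = 42))
sim$genotypes
#> genotype_table: 1500 individuals, 30 populations, 100 loci

div <- diversity_table(sim$genotypes)
head(div$per_population)
#>   population     He    Vp    k
#> 1     deme01 0.6721 1.811 5.55
#> 2     deme02 0.6633 1.741 5.46
#> 3     deme03 0.6369 1.669 5.12
#> ...

d0 <- distance_from_origin(sim$metadata, origin = c(0, 0),
                           origin_region = "G1", cfg = sim$waypoints)
diversity_distance_regression(div$per_population$He, d0)
#> OLS: slope = -4.849e-06 /km, R^2 = 0.6644, t = -7.445, p = 4.15e-08, n = 30

comb <- multilocus_combine(lapply(loci(sim$genotypes), function(l)
  three_level_amova(sim$genotypes, "stepwise", sim$hierarchy, l)))
round(100 * comb$indices, 2)
#>   RCT   RSC   RST
#> 18.17  4.84 22.13

permutation_test(sim$genotypes, "stepwise", "RST",
                 hierarchy = sim$hierarchy, n_perm = 999, seed = 7)$p
#> [1] 0.001

rey <- reynolds_transform(pairwise_matrix(sim$genotypes, "stepwise")$index)
mantel(rey, pairwise_geo_matrix(sim$metadata, sim$waypoints),
       n_perm = 999, seed = 7)
#> Mantel: r = 0.9848, one-tailed p = 0.001 (999 permutations)

nmds(rey, seed = 7)
#> nonmetric MDS: 30 points, stress-1 = 0.0288
```

Reading across the output: heterozygosity declines along the deme chain
(negative slope, two thirds of the He variation explained by distance
from the origin deme), 22% of the molecular variance lies among
populations — 18% of it among the 5 geographic groups — with a
permutation p at its floor, and genetic distances track routed
geographic distances almost perfectly (Mantel r = 0.98) with a clean
2-D ordination (stress 0.03). These are the qualitative signatures the
analysis stack is built to detect, amplified here by the deliberately
strong drift settings of the reference simulation.

Real published tables enter through `read_frequency_table()` (long
CSV/TSV), `read_genotypes_genepop()` / `read_genotypes_csv()`, and
`read_metadata()`; `run_all(run_config(...))` (or a YAML file via
`read_run_config()`) executes the whole workflow — validation,
diversity, regressions, hierarchical AMOVA, pairwise matrices,
Reynolds, MDS, Mantel, HWE — and writes TSV tables plus a JSON summary.

See the methods vignette (`vignettes/strpopgen-methods.Rmd`) for the
models, estimators, permutation schemes and the design rationale of the
generators.

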