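---
title: "Population-genetic analysis of forensic STR data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic analysis of forensic STR data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Forensic genetics laboratories have typed a small panel of autosomal STR
(microsatellite) markers — the 13 CODIS core loci — in hundreds of
population samples worldwide. Two kinds of data result: published
allele-frequency tables (one spectrum per population and locus, with the
sample size in gene copies) and individual genotype profiles. Although
these markers were chosen to maximize individual discrimination rather
than to represent neutral genomic variation, the sheer geographic
coverage makes the data attractive for population-genetic questions:
does diversity decline with distance from East Africa, is genetic
distance structured by geography, and how much does marker ascertainment
distort fixation indices relative to randomly chosen genomic STRs?

`strpopgen` implements the full analysis stack for such data, in both
data modes, plus synthetic-data generators so that every stage can be
exercised and validated without access to the original online databases.

## Data model

* `freq_table` — long-format records (population, locus, allele,
  frequency, n_copies). Allele labels are repeat counts and may be
  non-integer for imperfect alleles (9.3 means 9 full repeats plus 3
  bases); they enter all repeat arithmetic at their literal decimal
  value. Each cell's frequencies must sum to 1 within a tolerance
  (default 1e-3, since published tables are rounded).
* `genotype_table` — complete-case diploid calls; individuals missing
  any call at the analyzed loci are dropped at read time and reported.
* `pop_metadata` — coordinates, a geographic-group label (the
  among-groups stratum), a routing region for waypoint lookup, and a
  manual `well_defined` curation flag that filters honor but never infer.

Analyses that need allele copies (AMOVA, permutation tests) reconstruct
integer copy counts from a frequency cell as `frequency * n_copies`,
reconciled to sum exactly to `n_copies` by largest-remainder rounding
(ties broken by allele order). When the frequencies derive from counts
the reconstruction is exact, which is what makes genotype-mode and
frequency-mode analyses agree to machine precision on matched data; on
genuinely rounded published tables the error is at most half a copy per
allele.

## Diversity indices

Within a population sample of `n` gene copies with allele frequencies
`p_i`:

* expected heterozygosity (unbiased): `He = n/(n-1) * (1 - sum(p_i^2))`;
* variance in repeat number: `Vp`, the sample variance (denominator
  `n-1`) of repeat values over the copies; from frequencies,
  `Vp = n/(n-1) * (sum f_a a^2 - (sum f_a a)^2)`, exactly equal to the
  copy-path variance when the frequencies are integral counts.

Group summaries report the mean and SD over member populations of the
per-population means. Differences among groups are tested with
Kruskal–Wallis (tie-corrected, chi-square approximation — adequate at
the group sizes of intended use) and between group pairs with Wilcoxon
rank-sum tests, Bonferroni-adjusted by the number of pairs.

Hardy–Weinberg equilibrium is tested per population and locus with a
Monte-Carlo exact test: the statistic is the Levene conditional
probability of the genotype array given the allele counts; the null is
sampled by re-pairing the observed copies at random, and
`p = (#{arrays with probability <= observed} + 1) / (n_draws + 1)`,
floored at `1/(n_draws+1)`. The direction (heterozygote excess or
deficit) compares the observed heterozygote count with its expectation
under random pairing. Default 10,000 draws for single tests; the
whole-dataset scan uses fewer (configurable) because it only feeds
rejection counts.

## Geographic distances and the origin regression

Between-landmass distances follow land migration routes, so pairwise
distances are routed through obligatory waypoints: Anadyr, Cairo,
Istanbul, Phnom Penh and Prince Rupert. Each routing region carries a
"gateway path", the ordered waypoint list toward the East African
origin area (e.g. North America: Anadyr, then Cairo). A
population-to-origin distance sums the great-circle legs through its
region's gateway path; a North American sample reaches Addis Ababa as
population → Anadyr → Cairo → Addis Ababa. For a pair of regions the
route follows one gateway path forward and the other backward after
stripping their shared suffix (the gateways both would pass anyway), so
no detour through the hub side is introduced. The full region table is
an assumption of this package — only the North-America example above is
canonical — and it is completely overridable in configuration. Great
circles use the haversine formula on a sphere of radius 6371 km; no
ellipsoid, which is ample at continental resolution. The default origin
is Addis Ababa at (9.03 N, 38.74 E), a fixture choice for "East Africa".

The diversity–distance relation is an ordinary least-squares regression
of a per-population index on routed distance from the origin, reported
as slope, determination coefficient R², and the two-sided t-test on the
slope.

## AMOVA and fixation indices

Allele copies are the analysis units. Under the stepwise mutation model
the distance between copies is the squared difference of repeat values,
so within-set sums of pairwise distances reduce to sums of squared
deviations from the set mean; under the identity model (0/1 distance)
they reduce to allele-count expressions. Stepwise distances yield the R
statistics (R_ST, R_SC, R_CT); identity distances their F analogues.

Two-level partition (among/within populations): with `P` populations,
`n_k` copies each, `N` total, SSDs give mean squares with `P-1` and
`N-P` df; `sigma2_within = MS_within`,
`sigma2_among = (MS_among - MS_within)/n'` with
`n' = (N - sum(n_k^2)/N)/(P-1)`, and the index is the among-share of the
total. The three-level partition adds the among-groups stratum with the
standard expected-mean-square coefficients; when every group contains a
single population the middle stratum has zero df and is flagged
degenerate, and when the hierarchy collapses to one group the
computation reduces exactly to the two-level partition. Negative
variance components are reported as computed, never truncated — only
the Reynolds transform clamps.

Multi-locus indices follow the variance-component summation approach:
locus-specific components are summed stratum by stratum over loci and
the indices recomputed from the sums. Per-locus p-values can be merged
with Fisher's combined probability test (`chi2 = -2 sum log p` on `2k`
df), which is why permutation p-values use the `(x+1)/(B+1)` estimator —
it can never return 0.

Permutation schemes follow the index under test: the global index
permutes copies (frequency mode) or whole individuals (genotype mode)
among populations — across groups when a hierarchy is present; R_SC
permutes units among populations within their group; R_CT permutes
whole populations among groups. Genotype mode applies one permutation
jointly to all loci; frequency mode permutes per locus, as the loci are
then independent samples. Defaults are 10,000 iterations for AMOVA
indices and 1,000 for the Mantel test.

Pairwise population matrices apply the two-level multi-locus index to
every pair; Reynolds coancestry distances are `D = -ln(1 - theta)` with
`theta` clamped to `[0, 1 - 1e-9]` so that undifferentiated pairs map
to 0 and fixed pairs stay finite.

## Spatial structure

Ordination uses nonmetric (rank-based) MDS in two dimensions minimizing
Kruskal's stress-1 — nonmetric because the quantity of interest is a
stress value, and because Reynolds distances are only rank-reliable.
The fit takes the best of 16 seeded starts (the classical metric
solution plus random configurations); zero off-diagonal distances are
raised to a relative 1e-9 floor, as the optimizer requires positive
dissimilarities. Outliers are removed only through an explicit exclusion
list, mirroring the practice of dropping a by-inspection outlier and
refitting; nothing is detected automatically.

The Mantel test correlates the off-diagonal upper triangles of the
genetic and geographic matrices and permutes rows and columns of one
matrix jointly; the p-value is one-tailed for positive association,
matching the isolation-by-distance hypothesis.

## Marker-ascertainment experiment

Forensic panels were assembled from maximally discriminating — high
heterozygosity — loci. The experiment quantifies what that choice does
to population-genetic summaries. From a locus pool it extracts the
top-k and bottom-k panels by mean He over population samples (unweighted
mean across samples, ties broken by locus name; the pooled-copies
variant used for forensic-style panel construction is available
separately as `build_ascertainment_pool()`). Each panel is scored by
mean He, the across-population variance of panel He, and the
multi-locus fixation index, and the ascertained panel is located as a
percentile within `n_random` random k-panels. Variance comparisons
between datasets use the classic Levene test (mean centering; median —
Brown–Forsythe — by option) with a caller-supplied Bonferroni factor.

## Synthetic data: what it emulates and what it does not

Two generators define the package's reference study conditions.

**Serial-founder expansion** (`simulate_serial_founder`): a forward-time
Wright–Fisher chain of 30 demes of 200 diploids, each founded from 20
individuals of the previous deme, evolving 10 generations between
foundings, with 100 independent loci mutating at 5e-3 per copy per
generation under a strictly symmetric single-step model from an
ancestral repeat of 10. The founding cadence is deliberately fast
relative to the mutation-drift recovery time (about N generations):
that is the regime in which serial founding leaves a persistent
diversity gradient rather than a quickly saturating one, and it matches
the rapid-wavefront picture of the out-of-Africa expansion. The origin deme is burnt in for 1,000
generations, bringing He near its stepwise-model equilibrium
(`1 - 1/sqrt(1 + 8N mu)` ≈ 0.67) before the expansion starts. Each deme
is sampled (50 individuals) at the moment it founds its successor,
i.e. along the expansion wavefront. Demes sit on the equator 500 km
apart in 5 contiguous group blocks, so great-circle and along-line
distances agree. This produces the two signals the analyses assume:
declining He/Vp with distance from the origin, and hierarchical
population structure. A downward mutation at the repeat-1 floor is
suppressed (the copy stays at 1) — a biological floor that is
essentially unreachable at these settings. Not emulated: linkage,
selection, admixture, back-migration, realistic geography, and
mutation-rate heterogeneity among loci; passing tests therefore show
method correctness under a clean stepwise-drift model, not robustness
to every property of real forensic data.

**Balding–Nichols frequencies** (`simulate_balding_nichols`): population
allele frequencies drawn from a compound Dirichlet around an ancestral
spectrum with concentration `(1-F)/F`, then multinomial sampling of
gene copies. Expected F_ST equals the generating `F` and per-locus
expected He is `(1-F)` times ancestral He, giving analytic handles for
parameter-recovery tests (the estimator recovers F within 0.02 at
F ∈ {0.05, 0.1, 0.2} with 400 loci). Ancestral spectra, when not
supplied, vary across loci (4–10 consecutive integer alleles, symmetric
Dirichlet concentration 0.5–3), emulating the spread of diversities in
a random genomic STR panel.

For the ascertainment experiment the pool is generated with per-locus
`F` drawn from Unif(0.02, 0.35): real STR loci differ in mutation rate
by orders of magnitude, and faster loci are both more heterozygous and
less differentiated, so drift sensitivity varying by locus — with
observed He anti-correlated with it through the `(1-F)` factor — is
precisely the coupling that makes high-He ascertainment depress both
the across-population variance of He and the multi-locus fixation
index. A forward-simulated pool shows the same coupling through
stochastic drift alone, but the frequency-model pool makes the
mechanism explicit and keeps a 100-replicate experiment cheap.

## Numerical and design choices

* Copy-count reconstruction: largest remainder, allele-order
  tie-break; exact for count-derived frequencies.
* Negative variance components and negative indices are reported as
  computed; only `reynolds_transform()` clamps (to `[0, 1 - 1e-9]`).
* Permutation p-values: `(x+1)/(B+1)`, with a 1e-12 tolerance on the
  `>=` comparison so ties at machine precision count as exceedances.
* He tie-breaks in panel selection: locus name.
* GenePop allele codes map to repeat counts by integer value; a 4-digit
  extension (repeat × 10) carries decimal microvariants, since the
  2/3-digit dialect cannot encode 9.3.
* `--drop-complex-loci`-style robustness runs are supported by
  `drop_complex_loci()` (default FGA, D21S11, TH01) and by the
  `drop_loci` configuration key.
* One global seed per pipeline run, split deterministically per stage;
  every stage is a pure function of (inputs, configuration, seed).
* Group summary SDs are taken over populations (not loci); per-locus
  detail is exported alongside for transparency.
* Kruskal–Wallis uses the chi-square approximation; the Monte-Carlo
  HWE test and the permutation AMOVA are calibrated empirically in the
  test suite (type-I error 5% ± 2% under their nulls).

Test problem sizes are chosen to keep the whole suite desk-scale: the
oracle-equivalence sweeps use fixtures of at most 5 populations × 12
copies where a brute-force pairwise-distance computation is exact and
instant; simulation-based checks use the reference generator conditions
stated above.

## Known limitations

* Frequency mode cannot resolve within-individual structure, so no
  F_IS / inbreeding component is estimated anywhere; copies are treated
  as exchangeable within populations in both modes, which is what makes
  the modes commensurable.
* Allele-distance models are limited to stepwise and identity.
* The waypoint routing table beyond the canonical North-America example
  is an assumption; analyses of real data should review it.
* Published frequency tables rounded to fewer than three decimals can
  fail the sum-to-one check; the tolerance is configurable but
  deviations are then reported, not silently rescaled.
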