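---
title: "Methods: phenotypic and genetic differentiation in mixed-ploidy microsatellite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic and genetic differentiation in mixed-ploidy microsatellite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Common reed (*Phragmites australis*) forms wild populations that mix
cytotypes: invasive stands carrying up to six distinct microsatellite
alleles per locus alongside native diploid stands. Two questions drive the
analysis this package implements. First, how genetically differentiated are
such populations at microsatellite loci when allele *dosage* is
unobservable — a fragment profile shows which alleles an individual
carries, never how many copies? Second, when the phenotypic differentiation
of quantitative traits among those same populations is compared with the
neutral molecular baseline, which traits look like targets of divergent
selection rather than products of drift?

`polydiff` provides the full chain: dosage-ambiguous diversity statistics,
Bruvo and Nei–Li genotype distances, the allele-size variance partition
R\_ST, nested variance components for morphometric traits with the
phenotypic differentiation statistic P\_ST and a heritability analogue, the
P\_ST–R\_ST contrast, ordination and tree displays, and Mantel tests of
isolation by distance — plus a synthetic-data module that generates inputs
with exactly the statistical structure the analysis assumes.

## Dosage-ambiguous genotypes

A genotype at a locus is a *set* of 1–8 distinct fragment sizes (class
`microsat_dataset`). All frequency-based statistics use **presence
weighting**: each distinct allele of an individual contributes one
observation, regardless of its unknown copy number. This is the simplest
documented estimator for polyploid fragment data and is applied uniformly —
to expected heterozygosity, PIC, and R\_ST — so that the statistics remain
mutually consistent. Consequences worth knowing:

* `H_O` is *phenotypic* heterozygosity — the fraction of genotypes showing
  at least two distinct alleles — because true heterozygosity is undefined
  without dosage. In high-ploidy groups `H_O` typically exceeds `H_E`,
  which is the pattern seen in real mixed-ploidy surveys.
* A locus counts as polymorphic in a population when at least two distinct
  alleles occur there; no 95% frequency criterion is applied, so `P` moves
  in steps of one locus.
* The summary's overall row reports both the mean of per-population `A`
  and `A_pooled`, the mean number of distinct alleles per locus pooled over
  all populations. The pooled value exceeds every per-population mean
  whenever populations carry partly disjoint allele sets; reporting both
  avoids conflating two quantities that are sometimes printed under one
  symbol.
* Allelic richness `A_R` uses hypergeometric rarefaction at the
  allele-observation level: the expected number of distinct alleles in a
  subsample of `g` observations, with `g` defaulting to the smallest
  per-(population, locus) observation count.

## Bruvo distance and the unequal-ploidy convention

The per-allele distance is `d = 1 − 2^(−|x|)` with `x` the size difference
in repeat units. Equal-cardinality allele sets are matched by minimum-cost
perfect matching (an exact bitmask dynamic program; sets are capped at 8
alleles). For unequal cardinality the package averages the two standard
conventions: the *genome addition* model pads the smaller set with copies
of its own alleles, the *genome loss* model pads it with the larger set's
alleles, and each model averages the minimal matching cost over all
distinct padded multisets (combinations with replacement, not ordered
tuples — each distinct padded genotype counts once). Averaging addition and
loss is the symmetric default when nothing is known about the mutational
direction of ploidy change; the test suite pins the whole convention
against an independent exhaustive enumeration for all set pairs of size
≤ 4.

Individual-level distances average per-locus values over loci scored in
both individuals (pairwise deletion). The population-level matrix used for
tree building is the mean inter-individual distance between populations —
mean linkage, recorded here because distance aggregation is a genuine
choice that tree software often leaves implicit.

## R_ST

Allele sizes are converted to repeat units; each distinct allele per
individual is one observation. Per locus,
`R_ST = (S̄ − S_W) / S̄`, where `S_W` is the pooled within-group variance
(within-group sums of squares over pooled degrees of freedom) and `S̄` the
total allele-size variance. The overall estimate averages per-locus values
weighted by observation counts and is clipped to `[0, 1]`; a jackknife over
loci supplies a standard error and confidence interval. The estimator is
deliberately the plain variance-partition form — no AMOVA permutation
machinery — because the target quantity is the stepwise-mutation analogue
of F\_ST, and the simulator provides a direct check: with between- and
within-population allele-size variances in ratio 1:2 the estimate must
approach 1/3.

Two caveats. R\_ST is invariant under allele-size translation and
consistent repeat-unit rescaling (tested properties), but it assumes sizes
sit on the repeat lattice. And because genotypes are distinct-allele
*sets*, collapsing duplicate draws inflates the realized within-population
variance slightly above its nominal value, so recovered R\_ST sits a little
below the raw variance-ratio expectation; the recovery test tolerances
account for this.

## The nested phenotype model, P_ST, and h²

Trait values follow a three-stage nested random-effects model:

```
Y = mu + region + population(region) + haplotype(population) + plant + error
```

Components are estimated by REML (`lme4`), with a Henderson-I
method-of-moments cross-check for balanced designs (the two agree within
1% on balanced data whenever no component is truncated). Negative
method-of-moments solutions are truncated at zero and flagged. Haplotype is
treated as a *random* component by default — the reference analysis prints
a haplotype variance, which only a random-effect reading produces — with a
`haplotype_fixed` flag for the fixed-effect reading. When every plant in a
population carries the same haplotype label the component is inestimable
and is fixed at zero with a flag.

With one measurement per plant (the default design), the plant effect is
the lowest stochastic level: the model's residual variance *is* the
among-plant component, and `v_residual` is reported as zero, flagged.
Replicated measurements (a `replicate` column) separate the two.

The phenotypic differentiation statistic is

```
P_ST = V_AP / (V_AP + 2 V_WP)
```

with `V_AP` the among-population component and `V_WP` the **among-plant**
component — not the residual. That identification reproduces six of the
seven published worked examples exactly at two decimals, which is the
evidence for it. The heritability analogue is the among-plant variance over
the total (all five components). Two published values resist both formulas
as defined: the reference plant-height h² prints as 0.094 where the column
computes to 0.620, and the leaf-width P\_ST prints as 0.39 although its
plant variance prints as 0 (the formula then gives 1; 0.39 is recovered
only if the haplotype component is used as `V_WP`). The package computes
the formulas as defined and the test suite asserts the computed values,
documenting rather than silently matching the two anomalies.

### The contrast

`pst_rst_contrast()` classifies each trait against the neutral baseline:
`P_ST > R_ST + t` suggests divergent selection, `P_ST < R_ST − t` uniform
(stabilizing) selection, and values inside the band are drift-consistent.
The default tolerance `t = 0.03` makes the band concrete where the source
analysis used only qualitative language ("comparable", "exceeded"); it is
configurable and reported in every output. Traits whose h² exceeds a
configurable threshold (default 0.25, separating the traits the reference
analysis called moderately heritable from the weakly heritable ones) are
flagged as local-adaptation candidates. No formal Q\_ST–F\_ST significance
test is attempted; the classification is descriptive.

## Duncan's multiple range test

Populations are ranked by mean; a range spanning `p` ordered means is
tested against `q(1 − alpha_p, p, df) · sqrt(MS_W / n_h)` with protection
level `alpha_p = 1 − (1 − alpha)^(p−1)`, pooled within-population mean
square, and harmonic-mean group size for unbalanced designs. Ranges
contained in a non-significant wider range are never declared significant
(the standard protection rule), and the result is a compact letter display.
With zero pooled variance, populations are distinct unless their means are
exactly equal. The implementation is validated against a direct
least-significant-range oracle on three-group fixtures.

## Ordination, trees, clustering, bimodality

* **PCoA** is classical scaling: double-center `−D²/2`, eigendecompose,
  scale eigenvectors by the root eigenvalues. Negative eigenvalues — which
  Bruvo matrices produce routinely — are dropped and reported (count and
  magnitude); no Cailliez/Lingoes correction is applied by default, since
  the displays are qualitative. Proportions explained are relative to the
  positive-eigenvalue total.
* **Neighbor joining** delegates to `ape::nj` (Studier–Keppler criterion;
  ties broken by that implementation) and then clamps negative branch
  lengths to zero, moving each deficit to the sibling branch so total tree
  length is preserved. Three-taxon input uses the closed-form three-point
  equations. On additive matrices the output reproduces the generating tree
  to `1e-9`.
* **Phenotype clustering** is average linkage on the standardized-Euclidean
  population distance (traits z-scored over all plants, population means on
  z-scores). Node support is the percentage of trait-resampled bootstrap
  replicates containing the node's population set — an ordinary bootstrap,
  coarse with seven traits, and intentionally so: it replaces
  multiscale-bootstrap machinery with a transparent resampling whose
  granularity is visible in the support values.
* **Bimodality screening** compares one- and two-component Gaussian
  mixtures (`mclust`): a sample is bimodal when the two-component model
  wins by more than 10 BIC (a strong-evidence margin) *and* both weights
  reach 0.1. A defined criterion replaces visual histogram inspection; on
  simulated data a bimodal flag indicates strong population structure in
  the trait, not a major gene.

## Mantel test

Pearson correlation of upper-triangle entries, with the null built by
jointly permuting rows and columns of the second matrix. The p-value uses
the add-one correction (never exactly zero) and is two-sided by default —
the direction of an isolation-by-distance effect is a conclusion, not an
assumption — with a one-sided option. Defaults: 10,000 permutations.
Genetic input is pairwise population R\_ST (a linearized
`R_ST/(1 − R_ST)` helper exists); geographic input is haversine
great-circle distance on a sphere of radius 6371.0088 km.

## The synthetic-data generator

`simulate_genotypes()` draws, per locus, a latent population mean on the
repeat lattice (spread `between_pop_sd`, in repeat units) and gives each
individual 1 to max-ploidy distinct alleles around that mean (spread
`within_pop_sd`, rounded to the lattice, with a small one-step jitter
rate). Defaults emulate the reference design: 20 populations (9
Kashmir-invasive, hexaploid cap; 10 Quebec-invasive, tetraploid cap; 1
Quebec-native, diploid cap) × 25 individuals × the nine-locus dinucleotide
panel with its published size ranges. The default spreads
(`between_pop_sd = 1`, `within_pop_sd = 1.35`) were chosen once so the
expected differentiation lands in the moderate-to-high range reported for
fragmented reed populations (overall R\_ST near 0.35) and were not revisited.

`simulate_phenotypes()` draws each trait as the grand mean plus independent
zero-mean normal effects per region, population, (population, haplotype)
combination, plant, and measurement, with the published variance components
as defaults on the 16-population × 25-plant phenotype design. The haplotype
effect is simulated as random (see above). Values are floored at zero to
respect trait non-negativity; with the default means and components the
floor is almost never active.

What the generator does *not* emulate: coalescent ancestry, linkage between
loci, selection, clonal resampling, spatially explicit dispersal, and any
systematic group-level allele-size shift between regions. Passing recovery
tests therefore demonstrates that the estimators invert the generator's
variance structure — not that real reed populations satisfy the model. In
particular the group-level (KE/QE/QN) R\_ST of synthetic data is near zero
by construction even when population-level R\_ST is high, and Mantel tests
on synthetic data have no spatial signal to find.

## Numerical choices and degenerate inputs

* Minimum-cost matching is exact (bitmask DP, `O(k·2^k)`, k ≤ 8).
* Frequencies must sum to 1 within `1e-6` (`pic()`); distance matrices must
  be symmetric within `1e-8` with zero diagonal.
* Monomorphic loci are undefined for per-locus R\_ST and are dropped from
  the weighted average; an entirely monomorphic dataset returns 0 with a
  warning. Zero-variance traits are excluded from distances and PCA with a
  warning. Pairs of individuals sharing no scored locus get `NA` distances,
  flagged.
* All stochastic operations take explicit integer seeds and are
  reproducible bit-for-bit; pipeline stage seeds are derived from the
  master seed by fixed offsets.

## Problem sizes used by the test suite

The suite exercises parameter recovery at the study design itself (16 × 25
phenotypes, 20 × 25 × 9 genotypes) with 20 seeded replicates per recovery
check, 1000 null pairs for Mantel calibration at 199 permutations each, and
100 seeds for the bimodality screen at n = 500 — sizes chosen to keep
Monte-Carlo error well inside each stated tolerance while the whole suite
runs in about a minute.

## Known limitations

* Presence weighting is a biased allele-frequency estimator when dosage
  varies; it is used for internal consistency, not optimality.
* R\_ST confidence intervals come from a locus jackknife; with nine loci
  they are coarse.
* The Bruvo unequal-ploidy convention (average of addition and loss over
  distinct paddings) is one of several in circulation; comparisons across
  software should fix the convention first.
* The bootstrap support for phenotype clustering resamples seven traits and
  can only take coarse values; it measures trait-consensus, not sampling
  error of plants.
* No attempt is made to resolve allele dosage, correct for null alleles, or
  test Hardy–Weinberg expectations.
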