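# polydiff

Phenotypic and genetic differentiation analysis for mixed-ploidy plant
populations genotyped at microsatellite loci with ambiguous allele dosage.

## The problem

In polyploid plants such as common reed (*Phragmites australis*), a
microsatellite fragment profile reveals *which* alleles an individual
carries but not their copy numbers, so standard codominant population
genetics does not apply directly. At the same time, deciding whether
quantitative traits diverged among populations through selection or drift
requires comparing phenotypic differentiation against a neutral molecular
baseline estimated from those same awkward genotypes.

`polydiff` implements the full analysis chain for this setting:

* **Diversity** — percentage of polymorphic loci *P*, mean alleles per
  locus *A* (and per polymorphic locus *A*<sub>p</sub>), rarefied allelic
  richness *A*<sub>R</sub> (hypergeometric), observed and expected
  heterozygosity under dosage-ambiguous presence weighting, PIC
  `1 − Σp²`, ploidy inference from allele counts, Fisher exact screens for
  gametic disequilibrium.
* **Distances** — Bruvo genotype distance
  (`d = 1 − 2^(−|x|)` per allele pair in repeat units, minimum-cost
  matching, genome addition/loss averaging for unequal ploidy), Nei–Li
  band-sharing distance `GD = 1 − 2N_xy/(N_x + N_y)`,
  standardized-Euclidean phenotype distance, haversine geographic
  distance.
* **Differentiation** — nested REML variance components
  (`Y = μ + region + population(region) + haplotype(population) + plant + e`),
  the phenotypic differentiation statistic
  **P<sub>ST</sub> = V<sub>AP</sub> / (V<sub>AP</sub> + 2 V<sub>WP</sub>)**,
  a heritability analogue (among-plant / total variance), the allele-size
  variance partition **R<sub>ST</sub> = (S̄ − S<sub>W</sub>) / S̄** with a
  locus jackknife, Duncan's multiple range test, and the
  P<sub>ST</sub>–R<sub>ST</sub> contrast classifying each trait as
  divergent-selection, drift-consistent, or uniform-selection.
* **Structure** — PCoA, neighbor-joining trees with Newick export,
  bootstrap-supported phenotype clustering, phenotype PCA,
  Gaussian-mixture bimodality screening.
* **Mantel** — permutation tests of isolation by distance.
* **Synthetic data** — generators for genotype, phenotype, and coordinate
  tables with exactly the nested statistical structure the estimators
  assume, so every stage is testable without raw field data.

## Worked example

P<sub>ST</sub> and the heritability analogue from published
variance-component estimates for reed leaf length (the package ships the
reference table):

```r
library(polydiff)
comp <- reed_trait_components()
v <- setNames(comp$leaf_length, comp$component)
pst(v[["population"]], v[["plant"]])
#> [1] 0.413393
heritability(v)
#> [1] 0.2781446
```

A leaf-length P<sub>ST</sub> of 0.41 against an overall R<sub>ST</sub> of
0.35 lands above the neutral band — the divergent-selection signature —
while its h² of 0.28 marks it as a moderately heritable local-adaptation
candidate.

End-to-end on synthetic data shaped like the study (20 populations × 25
individuals × 9 loci):

```r
ds <- simulate_genotypes(geno_sim_config(seed = 1))
r <- rst(ds)
round(r$overall, 3)
#> [1] 0.296
jk <- rst_jackknife(ds)
round(jk$ci, 3)
#> [1] 0.231 0.361

tab <- simulate_phenotypes(pheno_sim_config(seed = 2))
vc <- estimate_variance_components(tab, "leaf_length")
round(pst(vc), 2)
#> [1] 0.38
```

The simulator draws population allele-size spreads whose expected
differentiation is ≈ 0.35, and the estimator recovers it (0.296 with a
jackknife CI of 0.23–0.36 on this seed); the phenotype generator uses the
published leaf-length components (V<sub>AP</sub> = 38.83,
V<sub>WP</sub> = 27.55), and REML plus `pst()` recovers 0.38 against the
0.41 implied by the generating values.

`run_pipeline(pipeline_config(...), out_dir)` chains every stage and
writes CSV/JSON/Newick outputs plus a reproducibility manifest.

## The analysis workflow

`analysis/` holds the numbered drivers that reproduce the whole study
shape on synthetic data, writing all tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # genotypes, phenotypes, coordinates
Rscript analysis/02_diversity.R       # diversity, PIC, ploidy, LD screen
Rscript analysis/03_distances.R       # Bruvo, Nei–Li, geographic matrices
Rscript analysis/04_differentiation.R # components, P_ST, h2, R_ST, contrast
Rscript analysis/05_structure.R       # PCoA, NJ tree, clustering, PCA
Rscript analysis/06_mantel.R          # isolation by distance
```

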