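test_that("genotype simulation is deterministic and respects ploidy caps", {
  cfg <- geno_sim_config(seed = 7)
  ds1 <- simulate_genotypes(cfg)
  ds2 <- simulate_genotypes(cfg)
  expect_identical(ds1$calls, ds2$calls)
  ds3 <- simulate_genotypes(geno_sim_config(seed = 8))
  expect_false(identical(ds1$calls, ds3$calls))

  pop <- population_of(ds1)
  caps <- cfg$ploidy_by_group
  grp <- substr(pop, 1, 2)
  for (loc in ds1$loci$name) {
    lens <- vapply(ds1$calls[[loc]], length, integer(1))
    expect_true(all(lens <= caps[grp]))
    expect_true(all(lens >= 1))
  }
  qn_ids <- names(pop)[startsWith(pop, "QN")]
  qn_lens <- unlist(lapply(ds1$calls, function(cl)
    vapply(cl[qn_ids], length, integer(1))))
  expect_true(all(qn_lens <= 2))
})

test_that("zero spread collapses every genotype to the locus base size", {
  cfg <- geno_sim_config(n_populations = 4, n_individuals = 5, n_loci = 3,
                         group_of_population = rep("QE", 4),
                         between_pop_sd = 0, within_pop_sd = 0,
                         jitter_rate = 0, seed = 1)
  ds <- simulate_genotypes(cfg)
  for (loc in ds$loci$name) {
    sizes <- unique(unlist(ds$calls[[loc]]))
    expect_length(sizes, 1)
  }
  expect_warning(r0 <- rst(ds, pairwise = FALSE), "monomorphic")
  expect_equal(r0$overall, 0)
})

test_that("phenotype simulation is deterministic; zero variance gives mu", {
  cfg <- pheno_sim_config(seed = 5)
  expect_identical(simulate_phenotypes(cfg), simulate_phenotypes(cfg))

  comp0 <- reed_trait_components()
  for (tr in trait_names()) comp0[[tr]] <- rep(0, 5)
  cfg0 <- pheno_sim_config(components = comp0, seed = 2)
  tab <- simulate_phenotypes(cfg0)
  for (tr in trait_names())
    expect_true(all(tab[[tr]] == reed_trait_means()[[tr]]))
})

test_that("empirical variance components converge to configured values", {
  # large balanced design: 100 populations x 100 plants, one region
  comp <- reed_trait_components()
  for (tr in trait_names()) comp[[tr]] <- c(0, 38.83, 0, 27.55, 0)
  cfg <- pheno_sim_config(traits = "leaf_length", mu = c(leaf_length = 200),
                          components = comp,
                          pops_per_region = c(Quebec = 100),
                          plants_per_population = 100, seed = 41)
  tab <- simulate_phenotypes(cfg)
  vc <- estimate_variance_components(tab, "leaf_length")
  v <- setNames(vc$variance, vc$component)
  expect_lt(abs(v[["population"]] - 38.83) / 38.83, 0.25)  # 100 pops draw
  expect_lt(abs(v[["plant"]] - 27.55) / 27.55, 0.05)       # 10^4 plants
})

test_that("replicated measurements separate plant and residual variance", {
  comp <- reed_trait_components()
  cfg <- pheno_sim_config(traits = "fresh_mass",
                          measurements_per_plant = 4, seed = 6)
  tab <- simulate_phenotypes(cfg)
  expect_true("replicate" %in% names(tab))
  vc <- estimate_variance_components(tab, "fresh_mass")
  v <- setNames(vc$variance, vc$component)
  expect_gt(v[["residual"]], 0)
  expect_gt(v[["plant"]], 0)
})

test_that("simulated coordinates respect the bounding box and determinism", {
  co <- simulate_coordinates(20, 100, seed = 3)
  expect_identical(co, simulate_coordinates(20, 100, seed = 3))
  g <- geographic_matrix(co)
  pairs <- g[upper.tri(g)]
  expect_length(pairs, 190)                 # 20 * 19 / 2
  expect_true(all(pairs <= 100 * sqrt(2) * 1.05))

  co0 <- simulate_coordinates(5, 0, seed = 1)
  g0 <- geographic_matrix(co0)
  expect_true(all(g0 == 0))

  a <- data.frame(latitude = 45, longitude = -70)
  b <- data.frame(latitude = 46, longitude = -70)
  expect_equal(geographic_distance(a, b), 111.19, tolerance = 0.001)
})
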