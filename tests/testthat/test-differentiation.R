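test_that("variance components vanish on constant data", {
  tab <- toy_pheno(list(A = rep(5, 10), B = rep(5, 10)))
  vc <- estimate_variance_components(tab, "y")
  expect_true(all(vc$variance == 0))
})

test_that("REML recovers balanced two-level components", {
  # 16 populations x 25 plants, v_pop = 4, v_plant = 1: average estimates
  # over replicates stay within Monte-Carlo error of the truth
  est <- sapply(1:10, function(s) {
    tab <- rnorm_pheno(16, 25, v_pop = 4, v_plant = 1, seed = 100 + s)
    vc <- estimate_variance_components(tab, "y")
    setNames(vc$variance, vc$component)[c("population", "plant")]
  })
  # MC standard error of the mean of 10 replicate pop-variance estimates
  expect_lt(abs(mean(est["population", ]) - 4), 3 * sd(est["population", ]) /
              sqrt(10) + 0.5)
  expect_lt(abs(mean(est["plant", ]) - 1), 0.05)
})

test_that("REML and method-of-moments agree on balanced designs", {
  for (s in 1:3) {
    tab <- rnorm_pheno(8, 20, v_pop = 6, v_plant = 2, seed = 200 + s)
    vr <- estimate_variance_components(tab, "y")
    vm <- estimate_variance_components(tab, "y", method = "moments")
    for (comp in c("population", "plant")) {
      a <- vr$variance[vr$component == comp]
      b <- vm$variance[vm$component == comp]
      expect_lt(abs(a - b) / max(b, 1e-9), 0.01)
    }
  }
})

test_that("haplotype confounded with population is fixed at zero", {
  tab <- toy_pheno(list(A = rnorm(10, 10), B = rnorm(10, 12)),
                   haplotype_of = list(A = "inv", B = "nat"))
  vc <- estimate_variance_components(tab, "y")
  expect_equal(vc$variance[vc$component == "haplotype"], 0)
  expect_match(paste(attr(vc, "flags"), collapse = ";"), "confounded")
})

test_that("P_ST formula matches its definition and properties", {
  expect_equal(pst(38.83, 27.55), 38.83 / (38.83 + 2 * 27.55))
  expect_equal(pst(0, 5), 0)
  expect_equal(pst(3, 3), 1 / 3)
  expect_equal(pst(1e-6, 1e-6), 1 / 3)
  # monotone increasing in V_AP, decreasing in V_WP
  expect_gt(pst(5, 2), pst(4, 2))
  expect_lt(pst(4, 3), pst(4, 2))
  expect_error(pst(0, 0), "undefined")
})

test_that("heritability analogue divides plant variance by the total", {
  expect_equal(round(heritability(c(0.965, 0.371, 0, 0.555, 1.123)), 3),
               0.184)
  expect_equal(round(heritability(c(0, 6.07, 0, 6.08, 0.884)), 3), 0.466)
  expect_equal(heritability(c(1, 2, 3, 0, 4)), 0)
  expect_error(heritability(c(0, 0, 0, 0, 0)), "zero")
})

test_that("R_ST is zero without structure and one for fixed differences", {
  # identical allele multisets in every population
  per_pop <- list(c(100, 102), 104, 100, c(102, 104))
  calls <- list(L1 = c(per_pop, per_pop, per_pop))
  ds <- toy_dataset(calls, rep(c("A", "B", "C"), each = 4))
  expect_equal(rst(ds, pairwise = FALSE)$overall, 0)

  # populations fixed for different alleles
  ds2 <- toy_dataset(list(L1 = c(rep(list(100), 5), rep(list(120), 5))),
                     rep(c("A", "B"), each = 5))
  expect_equal(rst(ds2, pairwise = FALSE)$overall, 1)
})

test_that("R_ST is invariant to allele translation and unit rescaling", {
  cfg <- geno_sim_config(n_populations = 4, n_individuals = 10, n_loci = 3,
                         group_of_population = rep("KE", 4), seed = 17)
  ds <- simulate_genotypes(cfg)
  r0 <- rst(ds, pairwise = FALSE)$overall
  # translate all allele sizes by a constant
  ds_t <- ds
  ds_t$calls <- lapply(ds$calls, function(cl)
    lapply(cl, function(a) if (is.null(a)) NULL else a + 50L))
  expect_equal(rst(ds_t, pairwise = FALSE)$overall, r0, tolerance = 1e-12)
  # rescale sizes and repeat unit together
  ds_s <- ds
  ds_s$loci$repeat_unit <- ds$loci$repeat_unit * 3L
  ds_s$calls <- lapply(ds$calls, function(cl)
    lapply(cl, function(a) if (is.null(a)) NULL else a * 3L))
  expect_equal(rst(ds_s, pairwise = FALSE)$overall, r0, tolerance = 1e-12)
})

test_that("pairwise and jackknife R_ST behave coherently", {
  ds <- simulate_genotypes(geno_sim_config(seed = 23))
  r <- rst(ds, default_groups(ds))
  expect_true(all(diag(r$pairwise) == 0))
  expect_true(all(r$pairwise >= 0 & r$pairwise <= 1))
  expect_equal(r$pairwise, t(r$pairwise))
  expect_gt(max(r$pairwise), 0)   # default spread implies real structure
  jk <- rst_jackknife(ds)
  expect_gte(jk$se, 0)
  expect_true(jk$ci[1] <= jk$estimate && jk$estimate <= jk$ci[2])
})

test_that("the P_ST-R_ST contrast classifies traits against the band", {
  rep1 <- pst_rst_contrast(c(leaf_length = 0.41), c(leaf_length = 0.28),
                           0.35, tolerance = 0.03)
  expect_equal(rep1$classification, "divergent_selection")
  rep2 <- pst_rst_contrast(c(internode = 0.33), c(internode = 0.47),
                           0.35, tolerance = 0.03)
  expect_equal(rep2$classification, "drift_consistent")
  expect_true(rep2$local_adaptation)
  rep3 <- pst_rst_contrast(c(x = 0.35), c(x = 0.1), 0.35, tolerance = 0)
  expect_equal(rep3$classification, "drift_consistent")
  rep4 <- pst_rst_contrast(c(x = 0.12), c(x = 0.1), 0.35)
  expect_equal(rep4$classification, "uniform_selection")
})

test_that("Duncan letter displays collapse and separate correctly", {
  set.seed(51)
  tab_eq <- toy_pheno(list(A = rnorm(10, 10), B = rnorm(10, 10),
                           C = rnorm(10, 10)))
  d_eq <- duncan_mrt(tab_eq, "y")
  expect_true(all(d_eq$letters == "a"))

  tab_far <- toy_pheno(list(A = rnorm(10, 10, 0.5), B = rnorm(10, 60, 0.5),
                            C = rnorm(10, 110, 0.5)))
  d_far <- duncan_mrt(tab_far, "y")
  expect_equal(sort(d_far$letters), c("a", "b", "c"))

  # zero pooled variance: distinct unless means equal
  tab0 <- toy_pheno(list(A = rep(1, 5), B = rep(2, 5), C = rep(2, 5)))
  d0 <- duncan_mrt(tab0, "y")
  expect_equal(d0$letters[d0$population == "A"], "b")
  expect_true(all(d0$letters[d0$population %in% c("B", "C")] == "a"))
})

test_that("Duncan grouping matches the exhaustive three-group oracle", {
  scenarios <- list(
    c(0, 0.3, 0.8), c(0, 1.2, 2.4), c(0, 0.1, 3), c(0, 2.5, 5), c(0, 0, 0))
  for (k in seq_along(scenarios)) {
    set.seed(400 + k)
    mu <- 20 + scenarios[[k]]
    vals <- list(A = rnorm(12, mu[1]), B = rnorm(12, mu[2]),
                 C = rnorm(12, mu[3]))
    tab <- toy_pheno(vals)
    got <- duncan_mrt(tab, "y")
    want <- duncan_oracle3(vals)
    expect_equal(setNames(got$letters, got$population), want[got$population],
                 info = paste("scenario", k))
  }
})
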