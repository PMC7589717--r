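test_that("allele frequencies use presence weighting and sum to one", {
  ds <- toy_dataset(list(L1 = list(100, c(100, 102))), c("A", "A"))
  f <- allele_frequencies(ds)$L1
  expect_equal(unname(f[c("100", "102")]), c(2 / 3, 1 / 3))

  ds2 <- toy_dataset(list(L1 = list(100, 100, 100)), c("A", "A", "A"))
  expect_equal(unname(allele_frequencies(ds2)$L1), 1)

  # permutation of individuals leaves frequencies unchanged
  ds3 <- toy_dataset(list(L1 = list(c(100, 102), 100)), c("A", "A"))
  expect_equal(sort(allele_frequencies(ds3)$L1),
               sort(allele_frequencies(ds)$L1))

  # per-population scope sums to 1 within each population
  cfg <- geno_sim_config(n_populations = 3, n_individuals = 6, n_loci = 2,
                         group_of_population = rep("QE", 3), seed = 2)
  ds4 <- simulate_genotypes(cfg)
  fp <- allele_frequencies(ds4, "population")
  for (p in names(fp)) for (loc in names(fp[[p]]))
    expect_equal(sum(fp[[p]][[loc]]), 1)
})

test_that("PIC matches the 1 - sum(p^2) worked examples", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.5)
  expect_equal(pic(c(0.5, 0.3, 0.2)), 0.62)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
})

test_that("diversity summary reproduces small worked examples", {
  # 6 of 9 loci polymorphic -> P = 66.67
  calls <- c(
    lapply(1:6, function(i) list(100, 102)),     # polymorphic
    lapply(1:3, function(i) list(100, 100)))     # monomorphic
  names(calls) <- paste0("L", 1:9)
  ds <- toy_dataset(calls, c("A", "A"))
  dv <- diversity_summary(ds)
  expect_equal(dv$P[1], 100 * 6 / 9, tolerance = 1e-9)

  # two individuals {100}, {102}: A = 2, H_E = 0.5, H_O = 0
  ds2 <- toy_dataset(list(L1 = list(100, 102)), c("A", "A"))
  dv2 <- diversity_summary(ds2)
  expect_equal(dv2$A[1], 2)
  expect_equal(dv2$H_E[1], 0.5)
  expect_equal(dv2$H_O[1], 0)

  # all single-allele genotypes -> H_O = 0 everywhere
  ds3 <- toy_dataset(list(L1 = list(100, 102, 100, 102)),
                     c("A", "A", "B", "B"))
  dv3 <- diversity_summary(ds3)
  expect_true(all(dv3$H_O == 0))
})

test_that("rarefied richness is monotone in g and bounded by allele count", {
  counts <- c(10, 5, 2, 1)
  vals <- vapply(1:18, function(g) rarefied_richness(counts, g), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals <= length(counts) + 1e-12))
  expect_equal(rarefied_richness(counts, 18), 4)       # full sample
  expect_equal(rarefied_richness(counts, 1), 1)        # single draw
  expect_true(is.na(rarefied_richness(counts, 19)))
  ds <- simulate_genotypes(geno_sim_config(seed = 4))
  expect_error(diversity_summary(ds, rarefaction_g = 10000), "exceeds")
})

test_that("dropping a monomorphic locus changes P but not per-locus H_E", {
  calls <- list(L1 = list(100, 102, 100), L2 = list(200, 200, 200))
  ds <- toy_dataset(calls, c("A", "A", "A"))
  dv_all <- diversity_summary(ds)
  ds_poly <- toy_dataset(calls["L1"], c("A", "A", "A"))
  dv_poly <- diversity_summary(ds_poly)
  expect_lt(dv_all$P[1], dv_poly$P[1])
  # H_E of L1 is unchanged: with only L1, the mean over loci equals it
  f <- allele_frequencies(ds)$L1
  expect_equal(dv_poly$H_E[1], 1 - sum(f^2))
})

test_that("ploidy labels follow maximum distinct allele counts", {
  ds <- simulate_genotypes(geno_sim_config(seed = 11))
  pl <- infer_ploidy(ds, "group")
  expect_equal(unname(pl["KE"]), "hexaploid")
  expect_equal(unname(pl["QE"]), "tetraploid")
  expect_equal(unname(pl["QN"]), "diploid")

  ds2 <- toy_dataset(list(L1 = list(c(100, 102), 104)), c("A", "A"))
  expect_equal(unname(infer_ploidy(ds2)["A"]), "diploid")
  ds3 <- toy_dataset(list(L1 = list(c(100, 102, 104), 104)), c("A", "A"))
  expect_equal(unname(infer_ploidy(ds3)["A"]), "tetraploid")
})

test_that("gametic disequilibrium Fisher test matches its worked example", {
  # 10 individuals: first 5 carry major alleles at both loci, last 5 at
  # neither locus -> 2x2 table (5,0,0,5)
  callsA <- c(rep(list(c(100, 102)), 5), rep(list(104), 5))
  callsB <- c(rep(list(c(200, 202)), 5), rep(list(204), 5))
  # make 100 and 200 the most common alleles overall
  ds <- toy_dataset(list(LA = callsA, LB = callsB), rep("A", 10))
  res <- ld_fisher(ds, "LA", "LB")
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-5)

  # perfect association over n = 20 is highly significant
  callsA <- c(rep(list(100), 10), rep(list(102), 10))
  callsB <- c(rep(list(200), 10), rep(list(202), 10))
  ds2 <- toy_dataset(list(LA = callsA, LB = callsB), rep("A", 20))
  expect_lt(ld_fisher(ds2, "LA", "LB")$p, 0.001)

  # degenerate margin
  ds3 <- toy_dataset(list(LA = list(100, 100), LB = list(200, 202)),
                     c("A", "A"))
  expect_warning(r3 <- ld_fisher(ds3, "LA", "LB"), "degenerate")
  expect_equal(r3$p, 1)
})

test_that("Fisher screening is conservative-to-nominal under independence", {
  set.seed(31)
  ps <- replicate(200, {
    callsA <- lapply(1:24, function(i) sample(c(100, 102), 1))
    callsB <- lapply(1:24, function(i) sample(c(200, 202), 1))
    ds <- toy_dataset(list(LA = callsA, LB = callsB), rep("A", 24))
    suppressWarnings(ld_fisher(ds, "LA", "LB")$p)
  })
  expect_lte(mean(ps < 0.05), 0.07)
  expect_gt(mean(ps), 0.35)   # roughly uniform-to-conservative
})
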