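test_that("bruvo_pair matches closed forms on simple genotypes", {
  expect_equal(bruvo_pair(c(100, 102, 104), c(100, 102, 104), 2), 0)
  expect_equal(bruvo_pair(100, 102, 2), 0.5)          # one repeat step
  expect_equal(bruvo_pair(100, 104, 2), 0.75)         # two steps
  expect_equal(bruvo_pair(100, 100 + 2 * 20, 2), 1 - 2^(-20))
  expect_error(bruvo_pair(100, 102, 0), "repeat_unit")
  # symmetry
  expect_equal(bruvo_pair(c(100, 104), c(102, 106, 110), 2),
               bruvo_pair(c(102, 106, 110), c(100, 104), 2))
})

test_that("bruvo_pair stays within [0,1] and increases with divergence", {
  set.seed(12)
  for (i in 1:30) {
    a <- sort(sample(seq(100, 160, 2), sample(1:4, 1)))
    b <- sort(sample(seq(100, 160, 2), sample(1:4, 1)))
    v <- bruvo_pair(a, b, 2)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  shifts <- vapply(c(0, 2, 6, 12, 40), function(s)
    bruvo_pair(c(100, 104), c(100, 104) + s, 2), numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("bruvo_matrix composes per-locus pair distances", {
  calls <- list(
    L1 = list(c(100, 102), 100, c(104, 106), NULL, 102),
    L2 = list(200, c(200, 204), 202, 206, NULL))
  ds <- toy_dataset(calls, c("A", "A", "B", "B", "B"))
  expect_warning(bm <- bruvo_matrix(ds), "no scored locus")
  m <- unclass(bm$individual)
  # oracle: mean of per-locus bruvo_pair over loci present in both
  for (i in 1:4) for (j in (i + 1):5) {
    vals <- c()
    for (loc in names(calls)) {
      a <- calls[[loc]][[i]]; b <- calls[[loc]][[j]]
      if (!is.null(a) && !is.null(b))
        vals <- c(vals, bruvo_pair(a, b, 2))
    }
    if (length(vals)) {
      expect_equal(m[i, j], mean(vals), tolerance = 1e-12)
    } else {
      expect_true(is.na(m[i, j]))   # pair shares no scored locus
    }
  }
  # clone pair distance zero
  ds2 <- toy_dataset(list(L1 = list(c(100, 102), c(100, 102)),
                          L2 = list(200, 200)), c("A", "B"))
  expect_equal(unclass(bruvo_matrix(ds2)$individual)[1, 2], 0)
  # population matrix is the mean of inter-population entries
  expect_equal(unclass(bm$population)["A", "B"],
               mean(m[1:2, 3:5], na.rm = TRUE), tolerance = 1e-12)
})

test_that("bruvo_matrix is invariant under individual reordering", {
  cfg <- geno_sim_config(n_populations = 2, n_individuals = 5, n_loci = 3,
                         group_of_population = c("KE", "QE"), seed = 21)
  ds <- simulate_genotypes(cfg)
  perm <- c(7, 2, 9, 4, 1, 10, 3, 8, 5, 6)
  ds_p <- ds
  ds_p$individuals <- ds$individuals[perm, ]
  ds_p$calls <- lapply(ds$calls, function(cl) cl[perm])
  m1 <- unclass(bruvo_matrix(ds)$individual)
  m2 <- unclass(bruvo_matrix(ds_p)$individual)
  ids <- rownames(m1)
  expect_equal(m2[ids, ids], m1, tolerance = 1e-12)
})

test_that("band-sharing similarity and Nei-Li distance are complements", {
  expect_equal(genetic_similarity(1:3, 1:3), 1)
  expect_equal(genetic_similarity(1:3, 4:6), 0)
  expect_equal(genetic_similarity(1:4, 2:7), 0.6)      # 2*3 / (4+6)
  expect_equal(nei_li_distance(1:4, 2:7), 0.4)
  set.seed(8)
  for (i in 1:20) {
    x <- sample(letters, sample(2:10, 1))
    y <- sample(letters, sample(2:10, 1))
    expect_equal(genetic_similarity(x, y) + nei_li_distance(x, y), 1)
  }
  expect_error(genetic_similarity(character(0), character(0)), "empty")
})

test_that("standardized phenotype distance is scale-invariant", {
  set.seed(14)
  tab <- toy_pheno(list(A = rnorm(10, 10), B = rnorm(10, 12),
                        C = rnorm(10, 15)))
  d1 <- phenotype_euclidean(tab, "y")
  tab10 <- tab; tab10$y <- tab10$y * 10
  d2 <- phenotype_euclidean(tab10, "y")
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)
  # oracle: manual z-scoring and population means
  z <- (tab$y - mean(tab$y)) / sd(tab$y)
  mu <- tapply(z, tab$population, mean)
  expect_equal(d1["A", "B"], abs(mu[["A"]] - mu[["B"]]), tolerance = 1e-12)
  # identical populations at distance zero
  tab_eq <- toy_pheno(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_equal(unclass(phenotype_euclidean(tab_eq, "y"))["A", "B"], 0)
  # zero-variance trait excluded with warning
  tab$z <- 5
  expect_warning(phenotype_euclidean(tab, c("y", "z")), "zero variance")
})

test_that("great-circle distances match reference coordinates", {
  kp <- reed_populations()
  ke1 <- kp[kp$id == "KE1", ]; ke2 <- kp[kp$id == "KE2", ]
  expect_equal(geographic_distance(ke1, ke2), 2.4, tolerance = 0.1)
  expect_equal(geographic_distance(ke1, ke1), 0)
  g <- geographic_matrix(kp)
  expect_true(all(g >= 0))
  expect_true(max(g) > 9000)   # Kashmir to Quebec is intercontinental
})
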