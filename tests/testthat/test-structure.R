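test_that("classical scaling recovers Euclidean configurations", {
  # three collinear points: one positive eigenvalue, distances reproduced
  d <- dist_matrix(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3),
                   c("a", "b", "c"))
  p <- pcoa(d, 2)
  expect_equal(sum(p$eigenvalues > 1e-9), 1)
  expect_equal(as.matrix(dist(p$coordinates))[c("a", "b", "c"),
                                              c("a", "b", "c")],
               unclass(d), tolerance = 1e-9, ignore_attr = TRUE)

  # general Euclidean input reproduced exactly
  set.seed(5)
  x <- matrix(rnorm(20), 10, 2)
  rownames(x) <- paste0("p", 1:10)
  de <- dist_matrix(as.matrix(dist(x)))
  pe <- pcoa(de, 9)
  expect_equal(as.matrix(dist(pe$coordinates)), unclass(de),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lte(sum(pe$proportion_explained), 1 + 1e-9)
  expect_true(all(diff(pe$eigenvalues) <= 1e-9))

  # duplicate points coincide
  dd <- dist_matrix(matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3),
                    c("a", "b", "c"))
  pd <- pcoa(dd, 2)
  expect_equal(pd$coordinates["a", ], pd$coordinates["b", ],
               tolerance = 1e-9)
  # all-zero matrix gives zero coordinates
  p0 <- pcoa(dist_matrix(matrix(0, 3, 3), c("a", "b", "c")), 2)
  expect_true(all(p0$coordinates == 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(33)
  for (n in 4:8) {
    tr <- ape::unroot(ape::rtree(n))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(dist_matrix(D))
    expect_equal(ape::dist.topo(tr, est), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
})

test_that("three-taxon trees solve the three-point equations", {
  d3 <- dist_matrix(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3),
                    c("x", "y", "z"))
  tr <- nj_tree(d3)
  len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(len[["x"]], 1)
  expect_equal(len[["y"]], 2)
  expect_equal(len[["z"]], 3)
  expect_error(nj_tree(dist_matrix(matrix(0, 2, 2), c("a", "b"))), ">= 3")
})

test_that("label order does not change the NJ tree", {
  set.seed(44)
  x <- matrix(rnorm(12), 6, 2)
  rownames(x) <- paste0("P", 1:6)
  D <- as.matrix(dist(x))
  t1 <- nj_tree(dist_matrix(D))
  perm <- c(4, 2, 6, 1, 5, 3)
  t2 <- nj_tree(dist_matrix(D[perm, perm]))
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)
})

test_that("negative NJ branches are clamped without losing tree length", {
  # non-additive matrix known to produce a negative internal branch
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1e-6, 9, 10, 1e-6, 0),
              4, 4, dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(as.dist(D))
  tr <- nj_tree(dist_matrix(D))
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})

test_that("phenotype clustering assigns high support to clear clusters", {
  set.seed(61)
  mk <- function(mu) rnorm(12, mu, 1)
  vals <- list(A1 = mk(10), A2 = mk(11), B1 = mk(40), B2 = mk(41))
  tab <- toy_pheno(vals)
  tab$y2 <- tab$y + rnorm(nrow(tab), 0, 1)
  tab$y3 <- tab$y + rnorm(nrow(tab), 0, 1)
  hc <- hclust_phenotypes(tab, n_bootstrap = 200, seed = 9)
  expect_s3_class(hc$hclust, "hclust")
  expect_true(all(hc$support$support_pct >= 0 &
                    hc$support$support_pct <= 100))
  root <- which(vapply(strsplit(hc$support$members, ","), length,
                       integer(1)) == 4)
  expect_equal(hc$support$support_pct[root], 100)
  ab <- hc$support$members %in% c("A1,A2", "B1,B2")
  expect_true(all(hc$support$support_pct[ab] >= 95))
  # n_bootstrap = 0 still yields the dendrogram
  hc0 <- hclust_phenotypes(tab, n_bootstrap = 0)
  expect_true(all(is.na(hc0$support$support_pct)))
})

test_that("phenotype PCA has unit-norm loadings and sane proportions", {
  set.seed(71)
  tab <- toy_pheno(list(A = rnorm(30, 10), B = rnorm(30, 12)))
  tab$y2 <- 2 * tab$y            # perfectly correlated
  p <- suppressWarnings(pheno_pca(tab, c("y", "y2")))
  expect_equal(p$proportion[1], 100, tolerance = 1e-9)
  expect_equal(sum(p$proportion), 100, tolerance = 1e-9)
  for (j in seq_len(ncol(p$loadings)))
    expect_equal(sqrt(sum(p$loadings[, j]^2)), 1, tolerance = 1e-9)
  # orientation convention: dominant loading negative
  expect_lt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)

  tab$y3 <- rnorm(nrow(tab), 5)
  tab$y4 <- rnorm(nrow(tab), 5)
  p2 <- pheno_pca(tab, c("y", "y3", "y4"))
  expect_equal(sum(p2$proportion), 100, tolerance = 1e-9)
})

test_that("bimodality screening separates mixtures from single normals", {
  set.seed(81)
  mix <- c(rnorm(250, 0), rnorm(250, 6))
  expect_equal(bimodality_screen(mix)$verdict, "bimodal")
  uni <- rnorm(500)
  expect_equal(bimodality_screen(uni)$verdict, "unimodal")
  expect_equal(bimodality_screen(rep(3.2, 100))$verdict, "unimodal")
  expect_error(bimodality_screen(rnorm(10)), "n >= 20")
})
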