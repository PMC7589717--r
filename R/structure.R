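#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by
#' the square roots of their eigenvalues. Negative eigenvalues (possible
#' for non-Euclidean inputs such as Bruvo matrices) are dropped and
#' reported; no Cailliez/Lingoes correction is applied.
#'
#' @param d A distance matrix ([dist_matrix()] or plain symmetric matrix).
#' @param n_axes Number of axes to return (capped at the positive-
#'   eigenvalue count).
#' @return Object of class `pcoa_result`: list with `coordinates`,
#'   `eigenvalues` (all), `proportion_explained` (per returned axis,
#'   relative to the positive-eigenvalue total), and `negative_eigenvalues`
#'   (count and summed magnitude).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  b <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% b %*% ctr
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  ev <- eig$values
  pos <- which(ev > max(ev[1], 0) * 1e-12 & ev > 0)
  k <- min(n_axes, length(pos))
  coords <- if (k > 0) {
    eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(ev[pos[seq_len(k)]]), k)
  } else matrix(0, n, n_axes)
  rownames(coords) <- labels
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  prop <- if (length(pos)) ev[pos[seq_len(k)]] / sum(ev[pos]) else
    rep(0, ncol(coords))
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = prop,
                 negative_eigenvalues = list(
                   count = sum(ev < -1e-12),
                   magnitude = sum(abs(ev[ev < -1e-12])))),
            class = "pcoa_result")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch lengths
#' are clamped to zero with the deficit moved to the sibling branch so the
#' total tree length is preserved. Three-taxon input is solved by the
#' closed-form three-point equations.
#'
#' @param d Distance matrix with at least 3 labels.
#' @return An \pkg{ape} `phylo` tree (unrooted, branch lengths >= 0).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need >= 3 labels", call. = FALSE)
  if (n == 3) {
    # three-point equations: a = (d12 + d13 - d23)/2, etc.
    a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    c_ <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                        rownames(d)[1], a, rownames(d)[2], b,
                                        rownames(d)[3], c_))
  } else {
    tr <- ape::nj(stats::as.dist(d))
  }
  clamp_negative_branches(tr)
}

# set negative edge lengths to 0 and add the deficit to the sibling edge
clamp_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      s <- sibs[1]
      tr$edge.length[s] <- tr$edge.length[s] + abs(deficit)
    }
  }
  tr
}

#' Write a tree in Newick format
#' @param tree An \pkg{ape} `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Average-linkage clustering of populations with bootstrap support
#'
#' Clusters populations on the standardized-Euclidean phenotype distance
#' (see [phenotype_euclidean()]) with average linkage. Node support is the
#' percentage of trait-resampled bootstrap replicates (traits drawn with
#' replacement) whose clustering contains the node's population set.
#'
#' @param table Phenotype data frame.
#' @param n_bootstrap Number of bootstrap replicates (0 for none).
#' @param seed Integer seed for the resampling.
#' @return List with `hclust` (the dendrogram), `support` (data frame:
#'   node, members, support_pct), and `distance` (the matrix used).
#' @export
hclust_phenotypes <- function(table, n_bootstrap = 1000, seed = 1L) {
  table <- validate_phenotypes(table)
  traits <- attr(table, "traits")
  d <- phenotype_euclidean(table, traits)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  clades <- dendro_clades(hc)
  support <- rep(NA_real_, length(clades))
  if (n_bootstrap > 0) {
    set.seed(as.integer(seed))
    hits <- numeric(length(clades))
    keys <- vapply(clades, function(s) paste(sort(s), collapse = "|"),
                   character(1))
    for (b in seq_len(n_bootstrap)) {
      tr_b <- sample(traits, length(traits), replace = TRUE)
      tab_b <- table[, c("region", "population", "haplotype", "plant")]
      for (i in seq_along(tr_b)) tab_b[[paste0("t", i)]] <- table[[tr_b[i]]]
      db <- suppressWarnings(phenotype_euclidean(tab_b))
      hb <- stats::hclust(stats::as.dist(db), method = "average")
      kb <- vapply(dendro_clades(hb), function(s)
        paste(sort(s), collapse = "|"), character(1))
      hits <- hits + (keys %in% kb)
    }
    support <- 100 * hits / n_bootstrap
  }
  members <- vapply(clades, function(s) paste(sort(s), collapse = ","),
                    character(1))
  list(hclust = hc,
       support = data.frame(node = seq_along(clades), members = members,
                            support_pct = support,
                            stringsAsFactors = FALSE),
       distance = d)
}

# leaf-label sets of each internal node of an hclust tree
dendro_clades <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    take <- function(x) if (x < 0) hc$labels[-x] else sets[[x]]
    sets[[i]] <- c(take(hc$merge[i, 1]), take(hc$merge[i, 2]))
  }
  sets
}

#' PCA of phenotypic traits
#'
#' Principal components on the correlation matrix (z-scored traits,
#' plant-level records). Component signs are fixed so that the
#' largest-magnitude loading of each component is negative; the orientation
#' is cosmetic and reported, not meaningful.
#'
#' @param table Phenotype data frame.
#' @param traits Trait columns; default all. Zero-variance traits are
#'   excluded with a warning.
#' @return Object of class `pheno_pca`: list with `loadings`, `sdev`,
#'   `proportion` and `cumulative` (percent variance), and `scores`.
#' @export
pheno_pca <- function(table, traits = NULL) {
  table <- validate_phenotypes(table)
  if (is.null(traits)) traits <- attr(table, "traits")
  keep <- traits[vapply(traits, function(tr) {
    s <- stats::sd(table[[tr]], na.rm = TRUE)
    ok <- !is.na(s) && s > 0
    if (!ok) warning("trait '", tr, "' has zero variance; excluded")
    ok
  }, logical(1))]
  if (length(keep) < 2) stop("need >= 2 traits with variance", call. = FALSE)
  x <- table[, keep, drop = FALSE]
  cc <- stats::complete.cases(x)
  if (sum(cc) < 3) stop("need >= 3 complete plants", call. = FALSE)
  fit <- stats::prcomp(x[cc, ], center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(fit$rotation))) {
    i_max <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i_max, j] > 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  prop <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(list(loadings = fit$rotation, sdev = fit$sdev,
                 proportion = prop, cumulative = cumsum(prop),
                 scores = fit$x),
            class = "pheno_pca")
}

#' Screen a trait distribution for bimodality
#'
#' Fits one- and two-component Gaussian mixtures (unequal variances) and
#' declares the sample bimodal when the two-component model wins by a BIC
#' margin greater than `bic_margin` and both mixture weights are at least
#' `min_weight`. The mixture criterion replaces visual histogram
#' inspection with a defined, testable rule.
#'
#' @param values Numeric sample (n >= 20).
#' @param bic_margin Required BIC improvement (mclust convention: higher is
#'   better); default 10.
#' @param min_weight Minimum mixture weight; default 0.1.
#' @return List with `verdict` (`"unimodal"` or `"bimodal"`), `statistic`
#'   (BIC difference, 2-component minus 1-component), and the fitted
#'   mixture `parameters`.
#' @export
bimodality_screen <- function(values, bic_margin = 10, min_weight = 0.1) {
  values <- values[!is.na(values)]
  if (length(values) < 20) stop("need n >= 20", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(list(verdict = "unimodal", statistic = -Inf, parameters = NULL))
  }
  fit1 <- mclust::Mclust(values, G = 1, modelNames = "X", verbose = FALSE)
  fit2 <- tryCatch(
    mclust::Mclust(values, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit2)) {
    return(list(verdict = "unimodal", statistic = -Inf, parameters = NULL))
  }
  delta <- as.numeric(fit2$bic) - as.numeric(fit1$bic)
  weights_ok <- all(fit2$parameters$pro >= min_weight)
  verdict <- if (delta > bic_margin && weights_ok) "bimodal" else "unimodal"
  list(verdict = verdict, statistic = delta,
       parameters = fit2$parameters)
}
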