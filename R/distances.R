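# Bruvo genotype distance for dosage-ambiguous microsatellite data.
# Per-allele distance d = 1 - 2^(-|x|) with x the size difference in repeat
# units; allele sets are matched by minimum-cost perfect matching, and sets
# of unequal cardinality are handled by averaging the genome-addition model
# (pad the smaller set with copies of its own alleles) and the genome-loss
# model (pad with the larger set's alleles) over all distinct paddings.

# all multisets of size d drawn from x (columns of the returned matrix)
multisets_of <- function(x, d) {
  n <- length(x)
  if (d == 0L) return(matrix(numeric(0), nrow = 0, ncol = 1))
  idx <- utils::combn(n + d - 1L, d)            # stars and bars
  sel <- idx - (seq_len(d) - 1L)                # non-decreasing index tuples
  matrix(x[sel], nrow = d)
}

# exact minimum-cost perfect matching by bitmask dynamic programming
min_cost_matching <- function(cost) {
  k <- nrow(cost)
  full <- bitwShiftL(1L, k) - 1L
  dp <- rep(Inf, full + 1L)
  dp[1L] <- 0
  npop <- integer(full + 1L)                    # popcount per mask
  for (m in seq_len(full)) {
    npop[m + 1L] <- npop[bitwShiftR(m, 1L) + 1L] + bitwAnd(m, 1L)
  }
  for (mask in 0:(full - 1L)) {
    d0 <- dp[mask + 1L]
    if (!is.finite(d0)) next
    i <- npop[mask + 1L] + 1L                   # next row to assign
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) {
        nm <- bitwOr(mask, bit) + 1L
        cand <- d0 + cost[i, j]
        if (cand < dp[nm]) dp[nm] <- cand
      }
    }
  }
  dp[full + 1L]
}

bruvo_cost <- function(a, b, repeat_unit) {
  x <- abs(outer(a, b, "-")) / repeat_unit
  1 - 2^(-x)
}

#' Bruvo distance between two allele sets
#'
#' @param a,b Integer vectors of distinct fragment sizes in bp (non-missing
#'   genotypes).
#' @param repeat_unit Repeat motif length in bp.
#' @return Distance in `[0, 1]`.
#' @export
bruvo_pair <- function(a, b, repeat_unit) {
  if (repeat_unit <= 0) stop("repeat_unit must be > 0", call. = FALSE)
  a <- sort(unique(as.numeric(a))); b <- sort(unique(as.numeric(b)))
  if (!length(a) || !length(b)) stop("empty allele set", call. = FALSE)
  ka <- length(a); kb <- length(b)
  if (ka == kb) {
    if (ka == 1L) return(1 - 2^(-abs(a - b) / repeat_unit))
    return(min_cost_matching(bruvo_cost(a, b, repeat_unit)) / ka)
  }
  small <- if (ka < kb) a else b
  large <- if (ka < kb) b else a
  d <- length(large) - length(small)
  pad_mean <- function(pool) {
    pads <- multisets_of(pool, d)
    costs <- apply(pads, 2, function(extra) {
      s2 <- c(small, extra)
      min_cost_matching(bruvo_cost(s2, large, repeat_unit)) / length(large)
    })
    mean(costs)
  }
  (pad_mean(small) + pad_mean(large)) / 2   # addition and loss models
}

#' Bruvo distance matrices over individuals and populations
#'
#' Individual-level distances are the mean of per-locus [bruvo_pair()]
#' values over loci with data in both individuals; the population-level
#' matrix is the mean inter-individual distance between populations.
#' Identical genotype pairs are computed once per locus, which keeps the
#' matrix tractable on lattice-simulated data.
#'
#' @param dataset A `microsat_dataset`.
#' @return List with `individual` and `population` distance matrices
#'   ([dist_matrix()]); pairs sharing no scored locus are `NA` with a
#'   warning.
#' @export
bruvo_matrix <- function(dataset) {
  ids <- dataset$individuals$id
  n <- length(ids)
  total <- matrix(0, n, n)
  nloc <- matrix(0L, n, n)
  for (li in seq_len(nrow(dataset$loci))) {
    loc <- dataset$loci$name[li]
    ru <- dataset$loci$repeat_unit[li]
    cl <- dataset$calls[[loc]]
    keys <- vapply(cl, function(a)
      if (is.null(a)) NA_character_ else paste(a, collapse = ","),
      character(1))
    uk <- unique(keys[!is.na(keys)])
    usets <- lapply(strsplit(uk, ",", fixed = TRUE), as.integer)
    m <- length(uk)
    du <- matrix(0, m, m)
    if (m > 1) {
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        du[i, j] <- du[j, i] <- bruvo_pair(usets[[i]], usets[[j]], ru)
      }
    }
    ki <- match(keys, uk)
    scored <- !is.na(ki)
    dfull <- matrix(NA_real_, n, n)
    dfull[scored, scored] <- du[ki[scored], ki[scored], drop = FALSE]
    has <- !is.na(dfull)
    total[has] <- total[has] + dfull[has]
    nloc <- nloc + has
  }
  ind <- total / nloc
  diag(ind) <- 0
  if (any(nloc[upper.tri(nloc)] == 0))
    warning("some individual pairs share no scored locus; distances NA")
  dimnames(ind) <- list(ids, ids)

  pop <- population_of(dataset)
  pops <- dataset$populations$id
  pm <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    block <- ind[names(pop)[pop == pops[i]], names(pop)[pop == pops[j]],
                 drop = FALSE]
    pm[i, j] <- pm[j, i] <- mean(block, na.rm = TRUE)
  }
  list(individual = dist_matrix(ind),
       population = dist_matrix(pm))
}

#' Band-sharing genetic similarity
#'
#' `GS = 2 N_ij / (N_i + N_j)` where `N_ij` is the number of fragments
#' shared by the two individuals and `N_i`, `N_j` their fragment counts.
#'
#' @param i,j Character or integer vectors of fragment identifiers.
#' @return Similarity in `[0, 1]`.
#' @export
genetic_similarity <- function(i, j) {
  i <- unique(i); j <- unique(j)
  if (!length(i) && !length(j))
    stop("both fragment sets empty", call. = FALSE)
  2 * length(intersect(i, j)) / (length(i) + length(j))
}

#' Nei-Li genetic distance
#'
#' The complement of band-sharing similarity:
#' `GD = 1 - 2 N_xy / (N_x + N_y)`, so `GD = 1 - GS` identically.
#'
#' @inheritParams genetic_similarity
#' @param x,y Fragment sets.
#' @return Distance in `[0, 1]`.
#' @export
nei_li_distance <- function(x, y) 1 - genetic_similarity(x, y)

#' Fragment (band) sets of each individual
#'
#' Union of observed alleles across loci, tagged by locus so equal sizes at
#' different loci stay distinct bands.
#'
#' @param dataset A `microsat_dataset`.
#' @return Named list of character vectors.
#' @export
fragment_sets <- function(dataset) {
  ids <- dataset$individuals$id
  stats::setNames(lapply(ids, function(ind) {
    unlist(lapply(dataset$loci$name, function(loc) {
      a <- dataset$calls[[loc]][[ind]]
      if (is.null(a)) character(0) else paste0(loc, ":", a)
    }), use.names = FALSE)
  }), ids)
}

#' Nei-Li distance matrix over individuals
#' @param dataset A `microsat_dataset`.
#' @return A [dist_matrix()] of pairwise `GD` values.
#' @export
nei_li_matrix <- function(dataset) {
  fs <- fragment_sets(dataset)
  n <- length(fs)
  m <- matrix(0, n, n, dimnames = list(names(fs), names(fs)))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- nei_li_distance(fs[[i]], fs[[j]])
    }
  }
  dist_matrix(m)
}

#' Standardized-Euclidean phenotype distance between populations
#'
#' Each trait is z-scored over all plants, population means are taken on
#' the z-scores, and Euclidean distances are computed between the
#' population mean vectors. Traits with zero variance are excluded with a
#' warning.
#'
#' @param table Phenotype data frame (see [validate_phenotypes()]).
#' @param traits Trait columns to use; default all present.
#' @return A [dist_matrix()] over populations.
#' @export
phenotype_euclidean <- function(table, traits = NULL) {
  table <- validate_phenotypes(table)
  if (is.null(traits)) traits <- attr(table, "traits")
  z <- population_zscores(table, traits)
  dist_matrix(as.matrix(stats::dist(z)))
}

# population mean matrix on z-scored traits (shared by distance + clustering)
population_zscores <- function(table, traits) {
  keep <- character(0)
  for (tr in traits) {
    s <- stats::sd(table[[tr]], na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("trait '", tr, "' has zero variance; excluded")
    } else keep <- c(keep, tr)
  }
  if (!length(keep)) stop("no trait with variance", call. = FALSE)
  z <- vapply(keep, function(tr) {
    x <- table[[tr]]
    (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  }, numeric(nrow(table)))
  z <- matrix(z, nrow = nrow(table), dimnames = list(NULL, keep))
  pops <- unique(table$population)
  out <- matrix(NA_real_, length(pops), length(keep),
                dimnames = list(pops, keep))
  for (p in pops)
    out[p, ] <- colMeans(z[table$population == p, , drop = FALSE],
                         na.rm = TRUE)
  out
}

#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param a,b Rows (or data frames) with `latitude` and `longitude` in
#'   decimal degrees.
#' @return Distance in km.
#' @export
geographic_distance <- function(a, b) {
  geosphere::distHaversine(
    cbind(a$longitude, a$latitude), cbind(b$longitude, b$latitude),
    r = 6371008.8) / 1000
}

#' Pairwise great-circle distance matrix
#' @param populations Data frame with `id`, `latitude`, `longitude`.
#' @return A [dist_matrix()] in km, labeled by `id`.
#' @export
geographic_matrix <- function(populations) {
  n <- nrow(populations)
  m <- matrix(0, n, n, dimnames = list(populations$id, populations$id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    m[i, j] <- m[j, i] <- geographic_distance(populations[i, ],
                                              populations[j, ])
  }
  dist_matrix(m)
}
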