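# Dosage-ambiguous convention used throughout: each distinct allele in an
# individual's genotype contributes one observation, regardless of (unknown)
# copy number.

#' Allele frequencies under dosage-ambiguous presence weighting
#'
#' @param dataset A `microsat_dataset`.
#' @param scope `"all"` for pooled frequencies per locus, `"population"` for
#'   a nested list population -> locus.
#' @return Named list per locus of named frequency vectors (allele size ->
#'   frequency, summing to 1); loci with no data are `NULL`.
#' @export
allele_frequencies <- function(dataset, scope = c("all", "population")) {
  scope <- match.arg(scope)
  freq_one <- function(calls) {
    obs <- unlist(calls, use.names = FALSE)
    if (!length(obs)) return(NULL)
    tab <- table(obs)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  if (scope == "all") {
    out <- lapply(dataset$calls, freq_one)
    return(out)
  }
  pop <- population_of(dataset)
  stats::setNames(lapply(dataset$populations$id, function(p) {
    ids <- names(pop)[pop == p]
    lapply(dataset$calls, function(cl) freq_one(cl[ids]))
  }), dataset$populations$id)
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2)` over the allele frequencies of a locus.
#'
#' @param frequencies Numeric vector of allele frequencies (sums to 1).
#' @return PIC in `[0, 1)`.
#' @export
pic <- function(frequencies) {
  frequencies <- as.numeric(frequencies)
  if (abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must sum to 1", call. = FALSE)
  1 - sum(frequencies^2)
}

#' Per-locus allele report
#'
#' Allele counts and observed size ranges per group plus pooled PIC per
#' locus, in the shape of a marker-panel summary table.
#'
#' @param dataset A `microsat_dataset`.
#' @param group_of Named character vector mapping population id to group
#'   label; defaults to the population `status`/`region` groups if present,
#'   else population id.
#' @return Data frame: one row per locus with per-group allele-count ranges,
#'   size ranges, and `pic`.
#' @export
locus_report <- function(dataset, group_of = NULL) {
  if (is.null(group_of)) group_of <- default_groups(dataset)
  pop <- population_of(dataset)
  grp <- group_of[pop]
  freqs <- allele_frequencies(dataset, "all")
  out <- lapply(dataset$loci$name, function(loc) {
    cl <- dataset$calls[[loc]]
    row <- data.frame(locus = loc, stringsAsFactors = FALSE)
    for (g in unique(group_of)) {
      cg <- cl[names(pop)[grp == g]]
      sizes <- unlist(cg, use.names = FALSE)
      counts <- vapply(cg, length, integer(1))
      counts <- counts[counts > 0]
      row[[paste0(g, "_size_range")]] <- if (length(sizes))
        paste0(min(sizes), "-", max(sizes)) else NA_character_
      row[[paste0(g, "_alleles")]] <- if (length(counts))
        paste0(min(counts), "-", max(counts)) else NA_character_
    }
    row$pic <- if (is.null(freqs[[loc]])) NA_real_ else pic(freqs[[loc]])
    row
  })
  do.call(rbind, out)
}

#' Region/status group labels of a dataset's populations
#'
#' Kashmir-invasive (`KE`), Quebec-invasive (`QE`), Quebec-native (`QN`)
#' when region and status metadata are present; population ids otherwise.
#' @param dataset A `microsat_dataset`.
#' @return Named character vector (population id -> group label).
#' @export
default_groups <- function(dataset) {
  p <- dataset$populations
  lab <- if (!is.null(p$region) && !is.null(p$status)) {
    ifelse(p$status == "native", "QN",
           ifelse(p$region == "Kashmir", "KE", "QE"))
  } else p$id
  stats::setNames(lab, p$id)
}

#' Rarefied allelic richness for one locus in one population
#'
#' Expected number of distinct alleles in a hypergeometric subsample of `g`
#' allele observations:
#' `A_R = sum_i [1 - choose(N - N_i, g) / choose(N, g)]`.
#'
#' @param counts Integer vector of per-allele observation counts.
#' @param g Subsample size (allele observations).
#' @return Expected allele count; `NA` when `g` exceeds the observation
#'   count.
#' @export
rarefied_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) return(NA_real_)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Per-population diversity summary
#'
#' For each population: sample size `n`, percentage of polymorphic loci
#' `P`, mean alleles per locus `A`, mean alleles per polymorphic locus
#' `A_p`, rarefied allelic richness `A_R`, observed heterozygosity `H_O`
#' (fraction of genotypes with at least two distinct alleles, averaged over
#' loci), and expected heterozygosity `H_E` (mean over loci of
#' `1 - sum p_i^2` on population-level presence frequencies). A locus is
#' polymorphic in a population when at least two distinct alleles occur.
#'
#' The summary row reports per-population column means plus `A_pooled`, the
#' mean number of distinct alleles per locus pooled over all populations
#' (which exceeds every per-population `A` whenever populations carry
#' different alleles).
#'
#' @param dataset A `microsat_dataset`.
#' @param rarefaction_g Allele-observation subsample size; default the
#'   smallest per-(population, locus) observation count.
#' @return Data frame, one row per population plus an `Overall` row;
#'   attribute `"rarefaction_g"` records the g used.
#' @export
diversity_summary <- function(dataset, rarefaction_g = NULL) {
  pop <- population_of(dataset)
  pops <- dataset$populations$id
  n_by_pop <- table(factor(pop, levels = pops))
  if (any(n_by_pop < 2))
    stop("every population needs >= 2 individuals", call. = FALSE)

  # per (pop, locus): observation counts per allele
  obs_counts <- lapply(pops, function(p) {
    ids <- names(pop)[pop == p]
    lapply(dataset$calls, function(cl) {
      sizes <- unlist(cl[ids], use.names = FALSE)
      if (!length(sizes)) return(integer(0))
      as.integer(table(sizes))
    })
  })
  names(obs_counts) <- pops
  all_N <- unlist(lapply(obs_counts, function(x) {
    n <- vapply(x, sum, numeric(1)); n[n > 0]
  }))
  g_min <- min(all_N)
  if (is.null(rarefaction_g)) rarefaction_g <- g_min
  if (rarefaction_g > g_min)
    stop("rarefaction_g (", rarefaction_g,
         ") exceeds the smallest observation count (", g_min, ")",
         call. = FALSE)

  rows <- lapply(pops, function(p) {
    ids <- names(pop)[pop == p]
    counts <- obs_counts[[p]]
    has_data <- vapply(counts, function(x) sum(x) > 0, logical(1))
    k_alleles <- vapply(counts, length, numeric(1))
    poly <- has_data & k_alleles >= 2
    he_by_locus <- vapply(dataset$loci$name, function(loc) {
      x <- counts[[loc]]
      if (!sum(x)) return(NA_real_)
      pfreq <- x / sum(x)
      1 - sum(pfreq^2)
    }, numeric(1))
    ho_by_locus <- vapply(dataset$loci$name, function(loc) {
      cl <- dataset$calls[[loc]][ids]
      len <- vapply(cl, length, integer(1))
      len <- len[len > 0]
      if (!length(len)) return(NA_real_)
      mean(len >= 2)
    }, numeric(1))
    ar_by_locus <- vapply(dataset$loci$name, function(loc) {
      x <- counts[[loc]]
      if (!sum(x)) return(NA_real_)
      rarefied_richness(x, rarefaction_g)
    }, numeric(1))
    data.frame(
      population = p,
      n = as.integer(n_by_pop[[p]]),
      P = 100 * sum(poly) / sum(has_data),
      A = mean(k_alleles[has_data]),
      A_p = if (any(poly)) mean(k_alleles[poly]) else NA_real_,
      A_R = mean(ar_by_locus, na.rm = TRUE),
      H_O = mean(ho_by_locus, na.rm = TRUE),
      H_E = mean(he_by_locus, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled_k <- vapply(dataset$calls, function(cl) {
    length(unique(unlist(cl, use.names = FALSE)))
  }, numeric(1))
  overall <- data.frame(
    population = "Overall", n = as.integer(round(mean(out$n))),
    P = mean(out$P), A = mean(out$A), A_p = mean(out$A_p, na.rm = TRUE),
    A_R = mean(out$A_R), H_O = mean(out$H_O), H_E = mean(out$H_E),
    stringsAsFactors = FALSE)
  out <- rbind(out, overall)
  out$A_pooled <- c(rep(NA_real_, length(pops)), mean(pooled_k[pooled_k > 0]))
  attr(out, "rarefaction_g") <- rarefaction_g
  rownames(out) <- NULL
  out
}

#' Infer ploidy from maximum distinct allele counts
#'
#' Maps the maximum number of distinct alleles observed in any genotype to
#' a cytotype label: up to 2 diploid, 4 tetraploid, 6 hexaploid, 8
#' octoploid.
#'
#' @param dataset A `microsat_dataset`.
#' @param scope `"population"` or `"group"` (region/status groups).
#' @return Named character vector of labels; attribute `"max_alleles"`
#'   holds the observed maxima.
#' @export
infer_ploidy <- function(dataset, scope = c("population", "group")) {
  scope <- match.arg(scope)
  pop <- population_of(dataset)
  unit <- if (scope == "population") pop else default_groups(dataset)[pop]
  labels <- unique(unit)
  maxima <- vapply(labels, function(u) {
    ids <- names(pop)[unit == u]
    lens <- unlist(lapply(dataset$calls, function(cl)
      vapply(cl[ids], length, integer(1))), use.names = FALSE)
    lens <- lens[lens > 0]
    if (!length(lens)) NA_integer_ else max(lens)
  }, integer(1))
  if (all(is.na(maxima))) stop("all genotypes missing", call. = FALSE)
  lab <- ifelse(is.na(maxima), NA_character_,
                ifelse(maxima <= 2, "diploid",
                       ifelse(maxima <= 4, "tetraploid",
                              ifelse(maxima <= 6, "hexaploid", "octoploid"))))
  structure(stats::setNames(lab, labels), max_alleles = maxima)
}

#' Fisher exact test of gametic disequilibrium between two loci
#'
#' Individuals with data at both loci are binarized by presence/absence of
#' each locus's most common allele (pooled frequencies; ties broken by
#' smallest size) and the 2x2 table is tested with a two-sided Fisher exact
#' test.
#'
#' @param dataset A `microsat_dataset`.
#' @param locusA,locusB Locus names.
#' @return List with `p`, the 2x2 `table`, and the `major_alleles` used.
#' @export
ld_fisher <- function(dataset, locusA, locusB) {
  stopifnot(locusA %in% dataset$loci$name, locusB %in% dataset$loci$name)
  clA <- dataset$calls[[locusA]]; clB <- dataset$calls[[locusB]]
  both <- names(clA)[!vapply(clA, is.null, logical(1)) &
                     !vapply(clB, is.null, logical(1))]
  if (length(both) < 2)
    stop("need >= 2 individuals with data at both loci", call. = FALSE)
  major <- function(cl) {
    tab <- table(unlist(cl[both], use.names = FALSE))
    sz <- as.integer(names(tab))
    sz[order(-as.integer(tab), sz)][1]  # most common; ties -> smallest size
  }
  mA <- major(clA); mB <- major(clB)
  a <- vapply(clA[both], function(x) mA %in% x, logical(1))
  b <- vapply(clB[both], function(x) mB %in% x, logical(1))
  tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; p set to 1")
    p <- 1
  } else {
    p <- stats::fisher.test(tab)$p.value
  }
  list(p = p, table = tab, major_alleles = c(mA, mB))
}
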