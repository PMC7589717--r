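# Small in-code fixtures and independent oracles shared across tests.

# dataset from explicit calls: `calls` is list(locus = list(alleles..., NULL))
toy_dataset <- function(calls, pops, repeat_unit = 2) {
  n <- length(pops)
  ids <- sprintf("i%02d", seq_len(n))
  loci <- do.call(rbind, lapply(names(calls), function(nm)
    locus_info(nm, repeat_unit)))
  calls <- lapply(calls, function(cl) stats::setNames(cl, ids))
  microsat_dataset(loci,
                   data.frame(id = unique(pops), stringsAsFactors = FALSE),
                   data.frame(id = ids, population = pops,
                              stringsAsFactors = FALSE),
                   calls)
}

# phenotype table from per-population value vectors (single trait "y")
toy_pheno <- function(values_by_pop, region_of = NULL, haplotype_of = NULL) {
  rows <- lapply(names(values_by_pop), function(p) {
    v <- values_by_pop[[p]]
    data.frame(
      region = if (is.null(region_of)) "R" else region_of[[p]],
      population = p,
      haplotype = if (is.null(haplotype_of)) "inv" else haplotype_of[[p]],
      plant = sprintf("p%02d", seq_along(v)),
      y = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- independent Bruvo oracle: recursive enumeration, no shared code ----

bruvo_oracle <- function(a, b, ru) {
  a <- sort(unique(a)); b <- sort(unique(b))
  da <- function(x, y) 1 - 2^(-abs(x - y) / ru)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  match_min <- function(s, l) {
    min(vapply(perms(seq_along(l)), function(p)
      sum(mapply(da, s, l[p])), numeric(1))) / length(l)
  }
  if (length(a) == length(b)) return(match_min(a, b))
  s <- if (length(a) < length(b)) a else b
  l <- if (length(a) < length(b)) b else a
  d <- length(l) - length(s)
  msets <- function(x, d) {
    out <- list()
    rec <- function(pref, start, left) {
      if (left == 0) { out[[length(out) + 1]] <<- pref; return(invisible()) }
      for (i in start:length(x)) rec(c(pref, x[i]), i, left - 1)
    }
    rec(numeric(0), 1, d)
    out
  }
  add_v <- mean(vapply(msets(s, d), function(e) match_min(c(s, e), l),
                       numeric(1)))
  los_v <- mean(vapply(msets(l, d), function(e) match_min(c(s, e), l),
                       numeric(1)))
  (add_v + los_v) / 2
}

# ---- two-sided Fisher oracle: hypergeometric tail enumeration ----

fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- direct Duncan oracle for exactly three groups ----

duncan_oracle3 <- function(values_by_group, alpha = 0.05) {
  means <- vapply(values_by_group, mean, numeric(1))
  vars <- vapply(values_by_group, stats::var, numeric(1))
  ns <- vapply(values_by_group, length, numeric(1))
  dfw <- sum(ns - 1)
  msw <- sum((ns - 1) * vars) / dfw
  nh <- 3 / sum(1 / ns)
  crit <- function(p) stats::qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, dfw) *
    sqrt(msw / nh)
  ord <- order(-means)
  m <- means[ord]
  sig13 <- (m[1] - m[3]) > crit(3)
  if (!sig13) {
    lets <- c("a", "a", "a")               # protected: nothing inside tested
  } else {
    sig12 <- (m[1] - m[2]) > crit(2)
    sig23 <- (m[2] - m[3]) > crit(2)
    lets <- if (!sig12 && !sig23) c("a", "ab", "b")
    else if (sig12 && !sig23) c("a", "b", "b")
    else if (!sig12 && sig23) c("a", "a", "b")
    else c("a", "b", "c")
  }
  stats::setNames(lets, names(means)[ord])
}

# balanced nested phenotype table drawn outside the package generator
rnorm_pheno <- function(n_pop, n_plant, v_pop, v_plant, mu = 50, seed = 1) {
  set.seed(seed)
  pops <- sprintf("P%02d", seq_len(n_pop))
  eff <- stats::rnorm(n_pop, 0, sqrt(v_pop))
  do.call(rbind, lapply(seq_len(n_pop), function(i) {
    data.frame(region = "R", population = pops[i], haplotype = "inv",
               plant = sprintf("p%02d", seq_len(n_plant)),
               y = pmax(mu + eff[i] + stats::rnorm(n_plant, 0, sqrt(v_plant)),
                        0),
               stringsAsFactors = FALSE)
  }))
}
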