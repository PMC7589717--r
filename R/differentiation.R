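#' Nested variance components for one trait
#'
#' Fits the nested random-effects model
#' `Y = mu + region + population(region) + haplotype(population) + plant +
#' error` by REML and reports the variance components. With one measurement
#' per plant the plant effect is the lowest stochastic level: its component
#' is the residual variance of the fit and `v_residual` is reported as 0
#' (flagged). Components whose factor has a single level, or whose grouping
#' duplicates a higher level (e.g. one haplotype per population), are fixed
#' at 0 with a warning.
#'
#' @param table Phenotype data frame (see [validate_phenotypes()]).
#' @param trait Trait column name.
#' @param haplotype_fixed Treat haplotype as a fixed effect (its variance
#'   reported as `NA`) instead of a random component.
#' @param method `"reml"` (default) or `"moments"` (Henderson I expected
#'   mean squares; balanced designs, region/population/plant levels only).
#' @return Object of class `variance_components`: data frame with columns
#'   `component`, `variance`, `flag`; attributes `trait` and `method`.
#' @export
estimate_variance_components <- function(table, trait,
                                         haplotype_fixed = FALSE,
                                         method = c("reml", "moments")) {
  method <- match.arg(method)
  table <- validate_phenotypes(table)
  stopifnot(trait %in% attr(table, "traits"))
  df <- table[!is.na(table[[trait]]), , drop = FALSE]
  if (length(unique(df$population)) < 2)
    stop("need >= 2 populations", call. = FALSE)
  df$y <- df[[trait]]
  df$pop <- factor(df$population)
  df$reg <- factor(df$region)
  df$hap <- factor(paste(df$population, df$haplotype))
  df$plant_uid <- factor(paste(df$population, df$plant))
  has_reps <- anyDuplicated(df$plant_uid) > 0

  flags <- character(0)
  use_region <- nlevels(df$reg) >= 2
  if (!use_region) flags <- c(flags, "region fixed at 0 (single level)")
  use_hap <- !haplotype_fixed && nlevels(df$hap) > nlevels(df$pop)
  if (!haplotype_fixed && !use_hap)
    flags <- c(flags, "haplotype fixed at 0 (confounded with population)")

  if (method == "moments") {
    vc <- moments_components(df, use_region)
    if (!use_region) flags <- unique(c(flags,
                                       "region fixed at 0 (single level)"))
    comp <- data.frame(
      component = c("region", "population", "haplotype", "plant", "residual"),
      variance = c(vc["region"], vc["population"], 0, vc["plant"], 0),
      stringsAsFactors = FALSE)
    flags <- c(flags, "haplotype fixed at 0 (moments method)",
               if (!has_reps) "residual folded into plant (one measurement per plant)")
  } else {
    terms <- c(if (use_region) "(1 | reg)", "(1 | pop)",
               if (use_hap) "(1 | hap)",
               if (has_reps) "(1 | plant_uid)")
    fixed <- if (haplotype_fixed && nlevels(factor(df$haplotype)) > 1)
      "haplotype" else "1"
    fml <- stats::as.formula(paste("y ~", fixed, "+",
                                   paste(terms, collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(g) {
      v <- vc$vcov[vc$grp == g]
      if (length(v)) v else 0
    }
    v_plant <- if (has_reps) getv("plant_uid") else getv("Residual")
    v_resid <- if (has_reps) getv("Residual") else 0
    if (!has_reps)
      flags <- c(flags,
                 "residual folded into plant (one measurement per plant)")
    comp <- data.frame(
      component = c("region", "population", "haplotype", "plant", "residual"),
      variance = c(if (use_region) getv("reg") else 0,
                   getv("pop"),
                   if (haplotype_fixed) NA_real_ else
                     if (use_hap) getv("hap") else 0,
                   v_plant, v_resid),
      stringsAsFactors = FALSE)
  }
  neg <- !is.na(comp$variance) & comp$variance < 0
  if (any(neg)) {
    flags <- c(flags, paste("truncated at 0:",
                            paste(comp$component[neg], collapse = ", ")))
    comp$variance[neg] <- 0
  }
  structure(comp, trait = trait, method = method, flags = flags,
            class = c("variance_components", "data.frame"))
}

# Henderson I / expected mean squares for the balanced nested design
# region > population > plant (one row per plant)
moments_components <- function(df, use_region) {
  n_per_pop <- table(df$pop)
  n <- mean(n_per_pop)
  grand <- mean(df$y)
  pop_mean <- tapply(df$y, df$pop, mean)
  ss_within <- sum((df$y - pop_mean[df$pop])^2)
  ms_plant <- ss_within / (nrow(df) - nlevels(df$pop))
  if (use_region) {
    reg_of_pop <- tapply(as.character(df$reg), df$pop, function(x) x[1])
    reg_mean <- tapply(df$y, df$reg, mean)
    b <- nlevels(df$pop) / nlevels(df$reg)  # pops per region (balanced)
    ss_pop <- sum(n_per_pop * (pop_mean - reg_mean[reg_of_pop])^2)
    ms_pop <- ss_pop / (nlevels(df$pop) - nlevels(df$reg))
    n_per_reg <- table(df$reg)
    ss_reg <- sum(n_per_reg * (reg_mean - grand)^2)
    ms_reg <- ss_reg / (nlevels(df$reg) - 1)
    v_pop <- (ms_pop - ms_plant) / n
    v_reg <- (ms_reg - ms_plant - n * v_pop) / (n * b)
  } else {
    ss_pop <- sum(n_per_pop * (pop_mean - grand)^2)
    ms_pop <- ss_pop / (nlevels(df$pop) - 1)
    v_pop <- (ms_pop - ms_plant) / n
    v_reg <- 0
  }
  c(region = v_reg, population = v_pop, plant = ms_plant)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components for", attr(x, "trait"),
      "(", attr(x, "method"), ")\n")
  print.data.frame(x)
  fl <- attr(x, "flags")
  if (length(fl)) cat("flags:", paste(fl, collapse = "; "), "\n")
  invisible(x)
}

#' Phenotypic differentiation statistic P_ST
#'
#' `P_ST = V_AP / (V_AP + 2 V_WP)` with `V_AP` the among-population and
#' `V_WP` the within-population (among-plant) variance component.
#'
#' @param v_ap Among-population variance, or a `variance_components` object
#'   (then `v_wp` is taken from its plant row).
#' @param v_wp Within-population (among-plant) variance.
#' @return P_ST in `[0, 1]`.
#' @export
pst <- function(v_ap, v_wp = NULL) {
  if (inherits(v_ap, "variance_components")) {
    v <- stats::setNames(v_ap$variance, v_ap$component)
    v_wp <- v[["plant"]]
    v_ap <- v[["population"]]
  }
  stopifnot(v_ap >= 0, v_wp >= 0)
  if (v_ap == 0 && v_wp == 0)
    stop("P_ST undefined: both components zero", call. = FALSE)
  v_ap / (v_ap + 2 * v_wp)
}

#' Heritability analogue
#'
#' Among-plant variance over total variance (sum of the region, population,
#' haplotype, plant, and residual components).
#'
#' @param components A `variance_components` object or numeric vector of
#'   the five components in the order region, population, haplotype, plant,
#'   residual.
#' @return h^2 in `[0, 1]`.
#' @export
heritability <- function(components) {
  v <- if (inherits(components, "variance_components")) {
    stats::setNames(components$variance, components$component)
  } else {
    stats::setNames(as.numeric(components),
                    c("region", "population", "haplotype", "plant",
                      "residual"))
  }
  v[is.na(v)] <- 0
  total <- sum(v)
  if (total <= 0) stop("total variance is zero", call. = FALSE)
  unname(v[["plant"]] / total)
}

#' R_ST: allele-size variance partition for microsatellites
#'
#' Allele sizes are converted to repeat units; each distinct allele of an
#' individual contributes one observation (dosage-ambiguous presence
#' weighting). Per locus, `R_ST = (S_bar - S_W) / S_bar` with `S_W` the
#' pooled within-group allele-size variance and `S_bar` the total variance;
#' the overall estimate averages per-locus values weighted by observation
#' counts and is clipped to `[0, 1]`.
#'
#' @param dataset A `microsat_dataset`.
#' @param grouping `"population"`, or a named character vector mapping
#'   population id to a custom group (e.g. region/status groups).
#' @param pairwise Also compute the matrix of pairwise group estimates.
#' @return List: `overall`, `per_locus` (data frame), and (if requested)
#'   `pairwise` matrix.
#' @export
rst <- function(dataset, grouping = "population", pairwise = TRUE) {
  pop <- population_of(dataset)
  grp <- if (identical(grouping, "population")) pop else {
    if (!all(pop %in% names(grouping)))
      stop("grouping must name every population id", call. = FALSE)
    stats::setNames(unname(grouping[pop]), names(pop))
  }
  if (length(unique(grp)) < 2) stop("need >= 2 groups", call. = FALSE)

  locus_stats <- function(ids_keep = NULL) {
    res <- lapply(seq_len(nrow(dataset$loci)), function(li) {
      loc <- dataset$loci$name[li]
      ru <- dataset$loci$repeat_unit[li]
      cl <- dataset$calls[[loc]]
      ids <- names(cl)[!vapply(cl, is.null, logical(1))]
      if (!is.null(ids_keep)) ids <- intersect(ids, ids_keep)
      if (!length(ids)) return(NULL)
      sizes <- unlist(cl[ids], use.names = FALSE) / ru
      g <- rep(grp[ids], vapply(cl[ids], length, integer(1)))
      n_obs <- length(sizes)
      if (n_obs < 2 || stats::var(sizes) == 0)
        return(data.frame(locus = loc, n_obs = n_obs, s_total = 0,
                          s_within = 0, rst = NA_real_))
      ss_w <- 0; df_w <- 0
      for (gg in unique(g)) {
        x <- sizes[g == gg]
        if (length(x) >= 2) {
          ss_w <- ss_w + sum((x - mean(x))^2)
          df_w <- df_w + length(x) - 1
        }
      }
      s_w <- if (df_w > 0) ss_w / df_w else 0
      s_t <- stats::var(sizes)
      data.frame(locus = loc, n_obs = n_obs, s_total = s_t, s_within = s_w,
                 rst = (s_t - s_w) / s_t)
    })
    do.call(rbind, res)
  }

  per_locus <- locus_stats()
  ok <- !is.na(per_locus$rst)
  if (!any(ok)) {
    warning("all loci monomorphic; R_ST set to 0")
    overall <- 0
  } else {
    overall <- stats::weighted.mean(per_locus$rst[ok],
                                    per_locus$n_obs[ok])
    overall <- min(max(overall, 0), 1)
  }
  out <- list(overall = overall, per_locus = per_locus)

  if (pairwise) {
    groups <- unique(grp)
    pm <- matrix(0, length(groups), length(groups),
                 dimnames = list(groups, groups))
    ids_by_grp <- split(names(grp), grp)
    if (length(groups) > 1) {
      for (i in 1:(length(groups) - 1)) for (j in (i + 1):length(groups)) {
        pl <- locus_stats(c(ids_by_grp[[groups[i]]], ids_by_grp[[groups[j]]]))
        okp <- !is.na(pl$rst)
        v <- if (any(okp))
          min(max(stats::weighted.mean(pl$rst[okp], pl$n_obs[okp]), 0), 1)
        else 0
        pm[i, j] <- pm[j, i] <- v
      }
    }
    out$pairwise <- pm
  }
  out
}

#' Jackknife over loci for R_ST
#'
#' Leave-one-locus-out estimates give a standard error and normal-theory
#' confidence interval for the overall R_ST.
#'
#' @inheritParams rst
#' @param conf Confidence level.
#' @return List with `estimate`, `se`, `ci`, and the leave-one-out values.
#' @export
rst_jackknife <- function(dataset, grouping = "population", conf = 0.95) {
  loci <- dataset$loci$name
  if (length(loci) < 2) stop("need >= 2 loci to jackknife", call. = FALSE)
  full <- rst(dataset, grouping, pairwise = FALSE)$overall
  loo <- vapply(loci, function(drop_loc) {
    ds <- dataset
    keep <- ds$loci$name != drop_loc
    ds$loci <- ds$loci[keep, , drop = FALSE]
    ds$calls <- ds$calls[ds$loci$name]
    rst(ds, grouping, pairwise = FALSE)$overall
  }, numeric(1))
  nl <- length(loci)
  se <- sqrt((nl - 1) / nl * sum((loo - mean(loo))^2))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = full, se = se,
       ci = c(max(0, full - zq * se), min(1, full + zq * se)),
       leave_one_out = loo)
}

#' Classify the P_ST - R_ST contrast per trait
#'
#' Traits whose P_ST exceeds the neutral expectation `R_ST` by more than
#' `tolerance` are classified as under divergent selection; traits within
#' the tolerance are consistent with drift; traits below suggest uniform
#' (stabilizing) selection. Traits with a heritability analogue above
#' `h2_threshold` are flagged as local-adaptation candidates.
#'
#' @param pst_by_trait Named numeric vector of P_ST values.
#' @param h2_by_trait Named numeric vector of h^2 values (same names).
#' @param rst_overall Overall R_ST.
#' @param tolerance Comparability band around R_ST (default 0.03).
#' @param h2_threshold Heritability flag threshold (default 0.25).
#' @return Data frame of class `differentiation_report` with columns
#'   `trait`, `pst`, `h2`, `classification`, `local_adaptation`; attributes
#'   `rst`, `tolerance`, `h2_threshold`.
#' @export
pst_rst_contrast <- function(pst_by_trait, h2_by_trait, rst_overall,
                             tolerance = 0.03, h2_threshold = 0.25) {
  stopifnot(length(pst_by_trait) >= 1, tolerance >= 0)
  traits <- names(pst_by_trait)
  h2 <- h2_by_trait[traits]
  cls <- ifelse(pst_by_trait > rst_overall + tolerance, "divergent_selection",
                ifelse(pst_by_trait < rst_overall - tolerance,
                       "uniform_selection", "drift_consistent"))
  out <- data.frame(trait = traits, pst = unname(pst_by_trait),
                    h2 = unname(h2), classification = unname(cls),
                    local_adaptation = unname(!is.na(h2) &
                                                h2 >= h2_threshold),
                    stringsAsFactors = FALSE)
  structure(out, rst = rst_overall, tolerance = tolerance,
            h2_threshold = h2_threshold,
            class = c("differentiation_report", "data.frame"))
}

#' Duncan's multiple range test
#'
#' Populations are ranked by trait mean and compared stepwise against
#' Duncan's least significant ranges: for a span of `p` ordered means the
#' critical range is `q(1 - alpha_p, p, df) * sqrt(MS_W / n_h)` with
#' protection level `alpha_p = 1 - (1 - alpha)^(p - 1)`, pooled
#' within-population mean square `MS_W`, and harmonic mean group size
#' `n_h`. Ranges contained in a non-significant wider range are declared
#' non-significant. Output is a compact letter display: populations sharing
#' a letter do not differ significantly.
#'
#' @param table Phenotype data frame.
#' @param trait Trait column.
#' @param alpha Nominal significance level (default 0.05).
#' @return Data frame `population`, `n`, `mean`, `letters` (means in
#'   decreasing order); attributes `ms_within`, `df`, `alpha`.
#' @export
duncan_mrt <- function(table, trait, alpha = 0.05) {
  table <- validate_phenotypes(table)
  stopifnot(trait %in% attr(table, "traits"))
  df0 <- table[!is.na(table[[trait]]), c("population", trait)]
  names(df0)[2] <- "y"
  n_g <- tapply(df0$y, df0$population, length)
  if (length(n_g) < 2 || any(n_g < 2))
    stop("need >= 2 populations with >= 2 plants each", call. = FALSE)
  means <- tapply(df0$y, df0$population, mean)
  vars <- tapply(df0$y, df0$population, stats::var)
  df_w <- sum(n_g - 1)
  ms_w <- sum((n_g - 1) * vars) / df_w
  n_h <- length(n_g) / sum(1 / n_g)

  ord <- order(-means)
  m <- means[ord]
  k <- length(m)
  if (ms_w == 0) {
    # zero pooled variance: populations differ iff their means differ
    letters_vec <- letter_display(outer(m, m, function(a, b)
      abs(a - b) > 0))
  } else {
    crit <- vapply(2:k, function(p) {
      stats::qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, df_w) *
        sqrt(ms_w / n_h)
    }, numeric(1))
    # significance of each ordered range, with containment protection
    sig <- matrix(FALSE, k, k)
    nonsig <- matrix(FALSE, k, k)
    for (span in k:2) {
      for (i in 1:(k - span + 1)) {
        j <- i + span - 1
        contained <- FALSE
        if (span < k) {
          for (i2 in 1:i) for (j2 in j:k) {
            if ((j2 - i2 + 1) > span && nonsig[i2, j2]) contained <- TRUE
          }
        }
        if (contained || (m[i] - m[j]) <= crit[span - 1]) {
          nonsig[i, j] <- TRUE
        } else sig[i, j] <- TRUE
      }
    }
    sigm <- matrix(FALSE, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sigm[i, j] <- sigm[j, i] <- sig[i, j]
    }
    letters_vec <- letter_display(sigm)
  }
  out <- data.frame(population = names(m), n = as.integer(n_g[names(m)]),
                    mean = unname(m), letters = letters_vec,
                    stringsAsFactors = FALSE)
  structure(out, ms_within = ms_w, df = df_w, alpha = alpha,
            n_harmonic = n_h)
}

# compact letter display from a significance matrix over means sorted in
# decreasing order: maximal runs of mutually non-significant neighbours
letter_display <- function(sig) {
  k <- nrow(sig)
  groups <- list()
  for (i in 1:k) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    groups[[length(groups) + 1]] <- i:j
  }
  # drop groups contained in an earlier one
  keep <- !vapply(seq_along(groups), function(a) {
    any(vapply(seq_along(groups), function(b)
      b != a && all(groups[[a]] %in% groups[[b]]), logical(1)))
  }, logical(1))
  groups <- groups[keep]
  letters_vec <- character(k)
  for (gi in seq_along(groups)) {
    lab <- letters[(gi - 1) %% 26 + 1]
    if (gi > 26) lab <- paste0(lab, (gi - 1) %/% 26)
    for (i in groups[[gi]])
      letters_vec[i] <- paste0(letters_vec[i], lab)
  }
  letters_vec
}
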