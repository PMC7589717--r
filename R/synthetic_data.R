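#' Reference microsatellite locus panel for common reed
#'
#' The nine PaGT dinucleotide loci used to genotype mixed-ploidy common reed
#' (*Phragmites australis*), with the fragment-size ranges observed across
#' the Kashmir-invasive, Quebec-invasive, and Quebec-native groups.
#'
#' @return Data frame with columns `name`, `repeat_unit`, `size_min`,
#'   `size_max`.
#' @export
reed_loci <- function() {
  do.call(rbind, list(
    locus_info("PaGT4", 2, 285, 297),
    locus_info("PaGT14", 2, 191, 209),
    locus_info("PaGT8", 2, 192, 196),
    locus_info("PaGT13", 2, 225, 237),
    locus_info("PaGT9", 2, 209, 247),
    locus_info("PaGT11", 2, 160, 166),
    locus_info("PaGT22", 2, 190, 226),
    locus_info("PaGT12", 2, 183, 190),
    locus_info("PaGT16", 2, 248, 325)
  ))
}

#' Reference sampling locations for common reed populations
#'
#' Twenty populations (nine invasive in Kashmir, ten invasive and one
#' native in Quebec) with decimal-degree coordinates and elevation.
#'
#' @return Data frame with columns `id`, `region`, `status`, `latitude`,
#'   `longitude`, `elevation`.
#' @export
reed_populations <- function() {
  dms <- function(s) parse_dms(s)
  df <- data.frame(
    id = c("KE1", "KE2", "KE3", "KE4", "KE5", "KE6", "KE7", "KE8", "KE9",
           "QE1", "QE3", "QE4", "QE6", "QE7", "QE8", "QN1", "QE9", "QE10",
           "QE11", "QE12"),
    region = c(rep("Kashmir", 9), rep("Quebec", 11)),
    status = c(rep("invasive", 15), "native", rep("invasive", 4)),
    lat_dms = c("34°5’19″ N", "34°4’11″ N",
                "34°3’51″ N", "34°3’46″ N",
                "34°12’1″ N", "34°13’40″ N",
                "34°50’5″ N", "34°37’19″ N",
                "34°8’9″ N", "47°20’27″ N",
                "46°14’27″ N", "45°21’49″ N",
                "45°17’53″ N", "46°11’45″ N",
                "46°41’47″ N", "45°2’29″ N",
                "45°23’57″ N", "45°30’54″ N",
                "45°54’36″ N", "47°20’27″ N"),
    lon_dms = c("74°30’44″ E", "74°30’5″ E",
                "74°29’59″ E", "74°29’15″ E",
                "74°21’35″ E", "74°27’43″ E",
                "74°30’52″ E", "74°30’57″ E",
                "74°27’57″ E", "70°5’41″ W",
                "72°33’6″ W", "72°55’50″ W",
                "72°18’32″ W", "71°54’40″ W",
                "71°18’13″ W", "74°27’47″ W",
                "73°45’43″ W", "73°18’16″ W",
                "73°10’35″ W", "70°5’46″ W"),
    elevation = c(1597, 1579, 1595, 1583, 1580, 1578, 1583, 1585, 1572,
                  6.7, 32.3, 97, 273, 123.7, 76.8, 47, 28.6, 20.3, 8, 6.7),
    stringsAsFactors = FALSE
  )
  df$latitude <- dms(df$lat_dms)
  df$longitude <- dms(df$lon_dms)
  df[, c("id", "region", "status", "latitude", "longitude", "elevation")]
}

#' Reference variance components for seven reed morphometric traits
#'
#' REML variance-component estimates (region, population-in-region,
#' haplotype-in-population, plant, residual) reported for the common-reed
#' field survey this package models. Units are squared trait units
#' (cm^2, mm^2, g^2). These serve as realistic defaults for the phenotype
#' simulator and as worked-example inputs for [pst()] and [heritability()].
#'
#' @return Data frame with a `component` column and one numeric column per
#'   trait (see [trait_names()]).
#' @export
reed_trait_components <- function() {
  data.frame(
    component = c("region", "population", "haplotype", "plant", "residual"),
    plant_height = c(0, 730.06, 20.76, 1227.30, 1.0096),
    stem_diameter = c(0.965, 0.371, 0, 0.555, 1.123),
    fresh_mass = c(0.366, 2.160, 0.140, 7.846, 0.932),
    dry_mass = c(0.37, 0.577, 0.051, 1.743, 0.879),
    leaf_length = c(31.5, 38.83, 0.0142, 27.55, 1.155),
    internode_length = c(0, 6.07, 0, 6.08, 0.884),
    leaf_width = c(0.69, 0.0298, 0.0233, 0, 0.1144),
    stringsAsFactors = FALSE
  )
}

#' Reference grand means for the seven traits
#'
#' Rounded overall means for the morphometric traits, used as simulator
#' baselines so synthetic values sit on a realistic scale.
#' @return Named numeric vector over [trait_names()].
#' @export
reed_trait_means <- function() {
  c(plant_height = 190, stem_diameter = 6, fresh_mass = 5, dry_mass = 2.5,
    internode_length = 14, leaf_length = 36, leaf_width = 1.8)
}

# ---- genotype simulation ----------------------------------------------------

#' Configuration for the genotype simulator
#'
#' Defaults emulate the study design the analysis assumes: 20 populations
#' (nine Kashmir-invasive with up to six alleles, ten Quebec-invasive with
#' up to four, one Quebec-native with up to two) of 25 individuals at the
#' nine-locus reed panel. Allele sizes live on the repeat-unit lattice, as
#' the stepwise-mutation framework behind R_ST requires. The default
#' between/within spread (1 and 1.35 repeat units) puts the expected
#' allele-size differentiation near the moderate-to-high level typical of
#' fragmented reed populations.
#'
#' @param n_populations,n_individuals,n_loci Design counts.
#' @param loci Locus panel data frame; trimmed/recycled to `n_loci`.
#' @param ploidy_by_group Named integer vector: maximum distinct alleles per
#'   genotype for each group.
#' @param group_of_population Character vector (length `n_populations`)
#'   assigning each population to a group named in `ploidy_by_group`.
#' @param between_pop_sd,within_pop_sd Allele-size spread in repeat units
#'   between population means and around them.
#' @param jitter_rate Per-allele probability of a one-step lattice mutation.
#' @param seed Integer seed.
#' @return List of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_populations = 20, n_individuals = 25,
                            n_loci = 9, loci = reed_loci(),
                            ploidy_by_group = c(KE = 6L, QE = 4L, QN = 2L),
                            group_of_population = NULL,
                            between_pop_sd = 1, within_pop_sd = 1.35,
                            jitter_rate = 0.01, seed = 1L) {
  stopifnot(n_populations >= 1, n_individuals >= 1, n_loci >= 1,
            between_pop_sd >= 0, within_pop_sd >= 0,
            jitter_rate >= 0, jitter_rate <= 1)
  if (is.null(group_of_population)) {
    group_of_population <- if (n_populations == 20 &&
                               setequal(names(ploidy_by_group),
                                        c("KE", "QE", "QN"))) {
      c(rep("KE", 9), rep("QE", 10), "QN")
    } else {
      rep(names(ploidy_by_group), length.out = n_populations)
    }
  }
  stopifnot(length(group_of_population) == n_populations,
            all(group_of_population %in% names(ploidy_by_group)))
  loci <- loci[rep(seq_len(nrow(loci)), length.out = n_loci), , drop = FALSE]
  loci$name <- make.unique(loci$name)
  structure(list(n_populations = n_populations,
                 n_individuals = n_individuals, n_loci = n_loci, loci = loci,
                 ploidy_by_group = ploidy_by_group,
                 group_of_population = group_of_population,
                 between_pop_sd = between_pop_sd,
                 within_pop_sd = within_pop_sd,
                 jitter_rate = jitter_rate, seed = as.integer(seed)),
            class = "geno_sim_config")
}

#' Simulate a mixed-ploidy microsatellite dataset
#'
#' Per locus, each population receives a latent mean allele size drawn on
#' the repeat lattice with spread `between_pop_sd`; each individual carries
#' `k` distinct alleles (`k` uniform on 1..group max ploidy) drawn around
#' the population mean with spread `within_pop_sd`, rounded to the lattice,
#' with rare one-step jitter mutations. Deterministic given the seed.
#'
#' @param config A [geno_sim_config()].
#' @return A `microsat_dataset`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "geno_sim_config"))
  set.seed(config$seed)
  grp <- config$group_of_population
  grp_tab <- table(factor(grp, levels = unique(grp)))
  pop_ids <- unlist(lapply(names(grp_tab), function(g)
    paste0(g, seq_len(grp_tab[[g]]))))
  pop_group <- rep(names(grp_tab), grp_tab)
  pops <- data.frame(id = pop_ids,
                     region = ifelse(startsWith(pop_ids, "K"),
                                     "Kashmir", "Quebec"),
                     status = ifelse(pop_group == "QN", "native", "invasive"),
                     stringsAsFactors = FALSE)
  inds <- data.frame(
    id = sprintf("%s_i%02d", rep(pop_ids, each = config$n_individuals),
                 rep(seq_len(config$n_individuals), config$n_populations)),
    population = rep(pop_ids, each = config$n_individuals),
    stringsAsFactors = FALSE)
  max_k <- config$ploidy_by_group[pop_group[match(inds$population, pop_ids)]]

  calls <- vector("list", nrow(config$loci))
  names(calls) <- config$loci$name
  for (i in seq_len(nrow(config$loci))) {
    ru <- config$loci$repeat_unit[i]
    base <- if (!is.na(config$loci$size_min[i]))
      round((config$loci$size_min[i] + config$loci$size_max[i]) / 2) else 200L
    pop_offset <- round(stats::rnorm(config$n_populations, 0,
                                     config$between_pop_sd))
    off_of_ind <- pop_offset[match(inds$population, pop_ids)]
    cl <- vector("list", nrow(inds))
    for (j in seq_len(nrow(inds))) {
      k <- sample.int(max_k[j], 1L)
      a_ru <- off_of_ind[j] + round(stats::rnorm(k, 0, config$within_pop_sd))
      if (config$jitter_rate > 0) {
        hit <- stats::runif(k) < config$jitter_rate
        a_ru[hit] <- a_ru[hit] + sample(c(-1L, 1L), sum(hit), replace = TRUE)
      }
      cl[[j]] <- pmax(base + ru * unique(a_ru), ru)
    }
    names(cl) <- inds$id
    calls[[i]] <- cl
  }
  microsat_dataset(loci = config$loci, populations = pops,
                   individuals = inds, calls = calls,
                   max_ploidy = max(config$ploidy_by_group))
}

# ---- phenotype simulation ---------------------------------------------------

#' Configuration for the phenotype simulator
#'
#' Phenotypes follow a nested random-effects model: trait value = grand mean
#' plus independent zero-mean normal effects for region, population within
#' region, haplotype within population, plant, and (if replicated
#' measurements are requested) a residual per measurement. The defaults are
#' the reference variance components of [reed_trait_components()] on the
#' study's phenotype design (16 populations: 5 Kashmir, 11 Quebec, one of
#' which is the native haplotype; 25 plants each; one measurement per
#' plant).
#'
#' @param traits Character vector of traits to simulate.
#' @param mu Named numeric vector of grand means.
#' @param components Data frame in the shape of [reed_trait_components()];
#'   rows region/population/haplotype/plant/residual.
#' @param pops_per_region Named integer vector: populations per region.
#' @param plants_per_population Plants sampled per population.
#' @param measurements_per_plant Replicate measurements per plant; with 1
#'   the residual is folded into the plant-level scatter.
#' @param native_populations Character vector of population ids carrying the
#'   native haplotype (default the last Quebec population).
#' @param seed Integer seed.
#' @return List of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(traits = trait_names(),
                             mu = reed_trait_means(),
                             components = reed_trait_components(),
                             pops_per_region = c(Kashmir = 5L, Quebec = 11L),
                             plants_per_population = 25L,
                             measurements_per_plant = 1L,
                             native_populations = NULL,
                             seed = 1L) {
  stopifnot(all(traits %in% names(components)),
            all(traits %in% names(mu)),
            all(c("region", "population", "haplotype", "plant", "residual")
                %in% components$component),
            all(pops_per_region >= 1), plants_per_population >= 1,
            measurements_per_plant >= 1)
  for (tr in traits)
    if (any(components[[tr]] < 0))
      stop("negative variance component for trait ", tr, call. = FALSE)
  structure(list(traits = traits, mu = mu, components = components,
                 pops_per_region = pops_per_region,
                 plants_per_population = as.integer(plants_per_population),
                 measurements_per_plant = as.integer(measurements_per_plant),
                 native_populations = native_populations,
                 seed = as.integer(seed)),
            class = "pheno_sim_config")
}

#' Simulate a phenotype table from the nested random-effects model
#'
#' @param config A [pheno_sim_config()].
#' @return Validated phenotype data frame: one row per plant (or per
#'   measurement when `measurements_per_plant > 1`, with a `replicate`
#'   column).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "pheno_sim_config"))
  set.seed(config$seed)
  regions <- names(config$pops_per_region)
  pop_region <- rep(regions, config$pops_per_region)
  pop_ids <- unlist(lapply(regions, function(r)
    sprintf("%s_P%02d", substr(r, 1, 1),
            seq_len(config$pops_per_region[[r]]))))
  native <- config$native_populations
  if (is.null(native)) native <- pop_ids[length(pop_ids)]
  hap <- ifelse(pop_ids %in% native, "native", "invasive")

  npop <- length(pop_ids)
  nper <- config$plants_per_population
  nrep <- config$measurements_per_plant
  df <- data.frame(
    region = rep(pop_region, each = nper * nrep),
    population = rep(pop_ids, each = nper * nrep),
    haplotype = rep(hap, each = nper * nrep),
    plant = sprintf("p%02d", rep(rep(seq_len(nper), each = nrep), npop)),
    stringsAsFactors = FALSE)
  if (nrep > 1) df$replicate <- rep(seq_len(nrep), npop * nper)

  comp <- config$components
  rowv <- function(tr, what) comp[[tr]][comp$component == what]
  plant_uid <- paste(df$population, df$plant)
  u_plants <- unique(plant_uid)
  for (tr in config$traits) {
    eff_region <- stats::setNames(
      stats::rnorm(length(regions), 0, sqrt(rowv(tr, "region"))), regions)
    eff_pop <- stats::setNames(
      stats::rnorm(npop, 0, sqrt(rowv(tr, "population"))), pop_ids)
    # haplotype nested in population: one draw per (population, haplotype)
    eff_hap <- stats::setNames(
      stats::rnorm(npop, 0, sqrt(rowv(tr, "haplotype"))), pop_ids)
    eff_plant <- stats::setNames(
      stats::rnorm(length(u_plants), 0, sqrt(rowv(tr, "plant"))), u_plants)
    # residual = measurement error, one draw per row (per measurement)
    resid <- stats::rnorm(nrow(df), 0, sqrt(rowv(tr, "residual")))
    val <- config$mu[[tr]] + eff_region[df$region] + eff_pop[df$population] +
      eff_hap[df$population] + eff_plant[plant_uid] + resid
    df[[tr]] <- pmax(unname(val), 0)
  }
  validate_phenotypes(df)
}

# ---- coordinates ------------------------------------------------------------

#' Simulate population coordinates
#'
#' Uniform points in a square of side `extent_km`, mapped to latitude and
#' longitude around a base point.
#'
#' @param n Number of populations (>= 2).
#' @param extent_km Side of the bounding box in km.
#' @param seed Integer seed.
#' @param ids Optional population ids.
#' @param base_lat,base_lon Lower-left corner of the box in decimal degrees.
#' @return Data frame with `id`, `latitude`, `longitude`.
#' @export
simulate_coordinates <- function(n, extent_km = 100, seed = 1L, ids = NULL,
                                 base_lat = 45, base_lon = -72) {
  stopifnot(n >= 2, extent_km >= 0)
  set.seed(as.integer(seed))
  km_per_deg <- 6371.0088 * pi / 180
  x <- stats::runif(n, 0, extent_km)
  y <- stats::runif(n, 0, extent_km)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  data.frame(id = ids,
             latitude = base_lat + y / km_per_deg,
             longitude = base_lon + x / (km_per_deg * cos(base_lat * pi / 180)),
             stringsAsFactors = FALSE)
}
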