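#' Assemble a pipeline configuration
#'
#' @param genotypes A `microsat_dataset`, a [geno_sim_config()], a genotype
#'   file path, or `NULL` to skip the genetic stages.
#' @param phenotypes A phenotype data frame, a [pheno_sim_config()], a CSV
#'   path, or `NULL` to skip the phenotypic stages.
#' @param coordinates Data frame with `id`, `latitude`, `longitude`;
#'   `NULL` falls back to coordinates carried by the genotype dataset's
#'   population table (isolation by distance is skipped without them).
#' @param rarefaction_g Allele-observation subsample for allelic richness
#'   (`NULL` = automatic).
#' @param contrast_tolerance Comparability band for the P_ST-R_ST contrast.
#' @param h2_threshold Local-adaptation heritability flag threshold.
#' @param n_perm Mantel permutations.
#' @param n_bootstrap Phenotype-clustering bootstrap replicates.
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, phenotypes = NULL,
                            coordinates = NULL, rarefaction_g = NULL,
                            contrast_tolerance = 0.03, h2_threshold = 0.25,
                            n_perm = 10000, n_bootstrap = 500, seed = 1L) {
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 coordinates = coordinates, rarefaction_g = rarefaction_g,
                 contrast_tolerance = contrast_tolerance,
                 h2_threshold = h2_threshold, n_perm = n_perm,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_genotypes <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "microsat_dataset")) return(x)
  if (inherits(x, "geno_sim_config")) return(simulate_genotypes(x))
  if (is.character(x)) return(read_genotypes(x))
  stop("cannot interpret genotype input", call. = FALSE)
}

resolve_phenotypes <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "pheno_sim_config")) return(simulate_phenotypes(x))
  if (is.data.frame(x)) return(validate_phenotypes(x))
  if (is.character(x)) return(read_phenotypes(x))
  stop("cannot interpret phenotype input", call. = FALSE)
}

#' Run the full differentiation pipeline
#'
#' Executes, for whichever inputs are present: diversity summaries, locus
#' report and ploidy inference, Bruvo distance matrices and PCoA, the
#' neighbor-joining population tree, R_ST (overall, pairwise, jackknife),
#' variance components with P_ST and the heritability analogue per trait,
#' Duncan letter displays, phenotype PCA, bimodality screening, phenotype
#' clustering with bootstrap support, the P_ST-R_ST contrast, and a Mantel
#' test of isolation by distance. Writes CSV/JSON/Newick outputs plus a
#' reproducibility manifest to `out_dir`. A stage failure aborts with a
#' stage-tagged error; outputs of earlier stages are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of in-memory results, one element per stage run.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  jwrite <- function(x, file) jsonlite::write_json(
    x, file.path(out_dir, file), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dataset <- stage("inputs", resolve_genotypes(config$genotypes))
  pheno <- stage("inputs", resolve_phenotypes(config$phenotypes))

  if (!is.null(dataset)) {
    res$diversity <- stage("diversity", {
      ds <- diversity_summary(dataset, config$rarefaction_g)
      utils::write.csv(ds, file.path(out_dir, "diversity.csv"),
                       row.names = FALSE)
      ds
    })
    res$loci <- stage("loci", {
      lr <- locus_report(dataset)
      utils::write.csv(lr, file.path(out_dir, "locus_report.csv"),
                       row.names = FALSE)
      pl <- infer_ploidy(dataset, "group")
      jwrite(as.list(pl), "ploidy.json")
      lr
    })
    res$rst <- stage("rst", {
      r_pop <- rst(dataset, "population")
      grp <- default_groups(dataset)
      r_grp <- if (length(unique(grp)) > 1) rst(dataset, grp) else NULL
      jk <- rst_jackknife(dataset)
      out <- list(overall = r_pop$overall,
                  pairwise_population = r_pop$pairwise,
                  group = if (!is.null(r_grp))
                    list(overall = r_grp$overall, pairwise = r_grp$pairwise),
                  jackknife = list(se = jk$se, ci = jk$ci))
      jwrite(out, "rst.json")
      out
    })
    res$bruvo <- stage("bruvo", {
      bm <- bruvo_matrix(dataset)
      write_dist_csv(bm$population,
                     file.path(out_dir, "bruvo_population.csv"))
      write_dist_phylip(bm$population,
                        file.path(out_dir, "bruvo_population.phy"))
      bm
    })
    res$pcoa <- stage("pcoa", {
      pc <- pcoa(res$bruvo$individual, n_axes = 3)
      utils::write.csv(
        data.frame(individual = rownames(pc$coordinates),
                   population = population_of(dataset)[
                     rownames(pc$coordinates)],
                   pc$coordinates),
        file.path(out_dir, "pcoa_coordinates.csv"), row.names = FALSE)
      pc
    })
    res$tree <- stage("nj_tree", {
      tr <- nj_tree(res$bruvo$population)
      write_newick(tr, file.path(out_dir, "nj_tree.nwk"))
      tr
    })
  }

  if (!is.null(pheno)) {
    traits <- attr(pheno, "traits")
    res$components <- stage("variance_components", {
      comps <- lapply(traits, function(tr)
        estimate_variance_components(pheno, tr))
      names(comps) <- traits
      tab <- lapply(comps, function(vc) {
        v <- stats::setNames(vc$variance, vc$component)
        list(components = as.list(v),
             pst = tryCatch(pst(vc), error = function(e) NA),
             h2 = tryCatch(heritability(vc), error = function(e) NA))
      })
      jwrite(tab, "variance_components.json")
      comps
    })
    res$duncan <- stage("duncan", {
      dl <- lapply(traits, function(tr) {
        d <- duncan_mrt(pheno, tr)
        d$trait <- tr
        d
      })
      dl <- do.call(rbind, dl)
      utils::write.csv(dl, file.path(out_dir, "duncan.csv"),
                       row.names = FALSE)
      dl
    })
    res$pca <- stage("pca", {
      p <- pheno_pca(pheno)
      utils::write.csv(
        data.frame(trait = rownames(p$loadings), p$loadings,
                   check.names = FALSE),
        file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(component = seq_along(p$proportion),
                   sdev = p$sdev, proportion_pct = p$proportion,
                   cumulative_pct = p$cumulative),
        file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
      p
    })
    res$bimodality <- stage("bimodality", {
      bs <- do.call(rbind, lapply(traits, function(tr) {
        b <- bimodality_screen(pheno[[tr]])
        data.frame(trait = tr, verdict = b$verdict,
                   bic_difference = b$statistic, stringsAsFactors = FALSE)
      }))
      utils::write.csv(bs, file.path(out_dir, "bimodality.csv"),
                       row.names = FALSE)
      bs
    })
    res$clustering <- stage("clustering", {
      hc <- hclust_phenotypes(pheno, n_bootstrap = config$n_bootstrap,
                              seed = config$seed + 101L)
      utils::write.csv(hc$support,
                       file.path(out_dir, "hclust_support.csv"),
                       row.names = FALSE)
      write_dist_csv(hc$distance,
                     file.path(out_dir, "phenotype_distance.csv"))
      hc
    })
  }

  if (!is.null(dataset) && !is.null(pheno)) {
    res$contrast <- stage("contrast", {
      pst_v <- vapply(res$components, function(vc)
        tryCatch(pst(vc), error = function(e) NA_real_), numeric(1))
      h2_v <- vapply(res$components, function(vc)
        tryCatch(heritability(vc), error = function(e) NA_real_), numeric(1))
      ok <- !is.na(pst_v)
      rep <- pst_rst_contrast(pst_v[ok], h2_v[ok], res$rst$overall,
                              tolerance = config$contrast_tolerance,
                              h2_threshold = config$h2_threshold)
      jwrite(list(rst = attr(rep, "rst"),
                  tolerance = attr(rep, "tolerance"),
                  traits = rep), "contrast.json")
      rep
    })
  }

  coords <- config$coordinates
  if (is.null(coords) && !is.null(dataset) &&
      !is.null(dataset$populations$latitude))
    coords <- dataset$populations
  if (!is.null(dataset) && !is.null(coords) &&
      all(dataset$populations$id %in% coords$id) && nrow(coords) >= 4) {
    res$mantel <- stage("mantel", {
      coords <- coords[match(dataset$populations$id, coords$id), ]
      geo <- geographic_matrix(coords)
      gen <- rst(dataset, "population")$pairwise
      gen <- gen[rownames(geo), rownames(geo)]
      mt <- mantel_test(dist_matrix(gen), geo, n_perm = config$n_perm,
                        seed = config$seed + 202L)
      jwrite(list(r = mt$r, r_squared = mt$r_squared, p = mt$p,
                  n_perm = mt$n_perm, n = mt$n), "mantel.json")
      mt
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("polydiff")),
    r_version = R.version.string,
    seed = config$seed,
    n_perm = config$n_perm,
    n_bootstrap = config$n_bootstrap,
    contrast_tolerance = config$contrast_tolerance,
    stages_run = names(res),
    timestamp = format(Sys.time(), tz = "UTC"))
  jwrite(manifest, "manifest.json")
  invisible(res)
}
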