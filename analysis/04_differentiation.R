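#!/usr/bin/env Rscript
# Stage 4: the inferential core. Nested variance components per trait,
# P_ST and the heritability analogue, overall/group R_ST with a jackknife
# over loci, Duncan letter displays, and the P_ST-R_ST contrast
# classification.

suppressPackageStartupMessages(library(polydiff))

dataset <- read_genotypes("results/data/genotypes_synthetic.csv",
                         populations = reed_populations())
pheno <- read_phenotypes("results/data/phenotypes_synthetic.csv")
out <- "results"

traits <- attr(pheno, "traits")
comps <- lapply(traits, function(tr) estimate_variance_components(pheno, tr))
names(comps) <- traits
tab <- do.call(rbind, lapply(traits, function(tr) {
  v <- setNames(comps[[tr]]$variance, comps[[tr]]$component)
  data.frame(trait = tr, t(v),
             pst = tryCatch(pst(comps[[tr]]), error = function(e) NA),
             h2 = tryCatch(heritability(comps[[tr]]),
                           error = function(e) NA))
}))
write.csv(tab, file.path(out, "variance_components.csv"), row.names = FALSE)
cat("Variance components, P_ST, and h2 per trait:\n")
print(tab[, c("trait", "population", "plant", "pst", "h2")], digits = 3)

r_pop <- rst(dataset, "population")
grp <- default_groups(dataset)
r_grp <- rst(dataset, grp)
jk <- rst_jackknife(dataset)
cat(sprintf("\nOverall R_ST = %.3f (jackknife SE %.3f, 95%% CI %.3f-%.3f)\n",
            r_pop$overall, jk$se, jk$ci[1], jk$ci[2]))
cat("Group-pair R_ST:\n")
print(round(r_grp$pairwise, 3))
write_dist_csv(dist_matrix(r_pop$pairwise),
               file.path(out, "rst_pairwise_population.csv"))
write.csv(r_pop$per_locus, file.path(out, "rst_per_locus.csv"),
          row.names = FALSE)

duncan <- do.call(rbind, lapply(traits, function(tr) {
  d <- duncan_mrt(pheno, tr)
  d$trait <- tr
  d
}))
write.csv(duncan, file.path(out, "duncan_letters.csv"), row.names = FALSE)
cat("\nDuncan groupings span",
    min(tapply(duncan$letters, duncan$trait,
               function(x) length(unique(x)))), "to",
    max(tapply(duncan$letters, duncan$trait,
               function(x) length(unique(x)))),
    "letter classes per trait.\n")

pst_v <- setNames(tab$pst, tab$trait)
h2_v <- setNames(tab$h2, tab$trait)
ok <- !is.na(pst_v)
contrast <- pst_rst_contrast(pst_v[ok], h2_v[ok], r_pop$overall)
write.csv(contrast, file.path(out, "pst_rst_contrast.csv"),
          row.names = FALSE)
cat(sprintf("\nP_ST-R_ST contrast at tolerance %.2f against R_ST = %.3f:\n",
            attr(contrast, "tolerance"), attr(contrast, "rst")))
print(contrast)
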