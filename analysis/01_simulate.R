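#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study. No raw genotypes or field
# measurements are distributed with the original survey, so every
# downstream stage runs on data simulated under the study design: 20
# populations x 25 individuals at 9 microsatellite loci (Kashmir-invasive
# up to hexaploid, Quebec-invasive up to tetraploid, the single Quebec
# native diploid), and phenotypes for 16 populations x 25 plants drawn
# from the nested random-effects model with the published variance
# components.

suppressPackageStartupMessages(library(polydiff))

seed <- 20260921L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

geno_cfg <- geno_sim_config(seed = seed)
dataset <- simulate_genotypes(geno_cfg)

# relabel simulated populations with the real sampling-site ids so the
# genotypes line up with the published coordinates
ref <- reed_populations()
grp_ref <- ifelse(ref$status == "native", "QN",
                  ifelse(ref$region == "Kashmir", "KE", "QE"))
grp_sim <- substr(dataset$populations$id, 1, 2)
map <- character(0)
for (g in unique(grp_sim))
  map[dataset$populations$id[grp_sim == g]] <- ref$id[grp_ref == g]
dataset$populations <- merge(data.frame(id = unname(map[
  dataset$populations$id])), ref, by = "id", sort = FALSE)
dataset$individuals$population <- unname(map[
  dataset$individuals$population])

write_genotypes(dataset, file.path(out, "genotypes_synthetic.csv"))

pheno_cfg <- pheno_sim_config(seed = seed + 1L)
pheno <- simulate_phenotypes(pheno_cfg)
write_phenotypes(pheno, file.path(out, "phenotypes_synthetic.csv"))

# real sampling locations are known, so geography is not simulated
coords <- reed_populations()
write.csv(coords, file.path(out, "coordinates.csv"), row.names = FALSE)

cat("Simulated", nrow(dataset$individuals), "individuals in",
    nrow(dataset$populations), "populations at", nrow(dataset$loci),
    "loci;", nrow(pheno), "phenotype records for",
    length(unique(pheno$population)), "populations.\n")
cat("Wrote genotype, phenotype, and coordinate tables under", out, "\n")
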