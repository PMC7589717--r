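#!/usr/bin/env Rscript
# Stage 3: genotype and geographic distance matrices. The Bruvo matrix is
# computed over 8 individuals per population (160 total) to keep the
# exhaustive unequal-ploidy matching tractable; the population-level
# matrix is the mean inter-individual distance.

suppressPackageStartupMessages(library(polydiff))

dataset <- read_genotypes("results/data/genotypes_synthetic.csv",
                         populations = reed_populations())
coords <- read.csv("results/data/coordinates.csv")
out <- "results"

keep <- unlist(lapply(split(dataset$individuals$id,
                            dataset$individuals$population), head, 8))
dataset$individuals <- dataset$individuals[
  dataset$individuals$id %in% keep, ]
dataset$calls <- lapply(dataset$calls, function(cl)
  cl[dataset$individuals$id])

bm <- bruvo_matrix(dataset)
write_dist_csv(bm$individual, file.path(out, "bruvo_individual.csv"))
write_dist_csv(bm$population, file.path(out, "bruvo_population.csv"))
write_dist_phylip(bm$population, file.path(out, "bruvo_population.phy"))
cat("Bruvo distances over", nrow(bm$individual), "individuals;",
    "population matrix spans",
    round(min(bm$population[upper.tri(bm$population)]), 3), "to",
    round(max(bm$population), 3), "\n")

nl <- nei_li_matrix(dataset)
write_dist_csv(nl, file.path(out, "nei_li_individual.csv"))
cat("Nei-Li band-sharing distances written for the same individuals.\n")

geo <- geographic_matrix(coords)
write_dist_csv(geo, file.path(out, "geographic_km.csv"))
cat("Geographic distances: within-region pairs up to",
    round(max(geo[1:9, 1:9]), 1), "km (Kashmir);",
    "between-region pairs reach", round(max(geo), 0), "km.\n")
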