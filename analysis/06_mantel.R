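#!/usr/bin/env Rscript
# Stage 6: isolation by distance. Mantel correlation between pairwise
# population R_ST and great-circle distance, overall and within each
# region, with 10,000 permutations.

suppressPackageStartupMessages(library(polydiff))

dataset <- read_genotypes("results/data/genotypes_synthetic.csv",
                         populations = reed_populations())
coords <- read.csv("results/data/coordinates.csv")
out <- "results"

gen <- dist_matrix(rst(dataset, "population")$pairwise)
coords <- coords[match(rownames(gen), coords$id), ]
geo <- geographic_matrix(coords)

run <- function(ids, label, seed) {
  g1 <- dist_matrix(unclass(gen)[ids, ids])
  g2 <- dist_matrix(unclass(geo)[ids, ids])
  mt <- mantel_test(g1, g2, n_perm = 10000, seed = seed)
  cat(sprintf("%-10s r = %+.3f, r^2 = %.3f, p = %.4f (n = %d)\n",
              label, mt$r, mt$r_squared, mt$p, mt$n))
  data.frame(scope = label, r = mt$r, r_squared = mt$r_squared, p = mt$p,
             n_populations = mt$n, n_perm = mt$n_perm)
}

res <- rbind(
  run(rownames(gen), "overall", 11),
  run(grep("^K", rownames(gen), value = TRUE), "Kashmir", 12),
  run(grep("^Q", rownames(gen), value = TRUE), "Quebec", 13))
write.csv(res, file.path(out, "mantel.csv"), row.names = FALSE)
cat("\nSimulated populations have no spatial genetic process, so the",
    "expected correlations are near zero; the overall test can pick up",
    "the region split when regional allele pools drift apart.\n")
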