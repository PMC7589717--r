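#!/usr/bin/env Rscript
# Stage 2: within-population diversity, marker informativeness, ploidy
# inference, and a gametic-disequilibrium screen on the synthetic
# genotypes from stage 1.

suppressPackageStartupMessages(library(polydiff))

dataset <- read_genotypes("results/data/genotypes_synthetic.csv",
                         populations = reed_populations())
out <- "results"

dv <- diversity_summary(dataset)
write.csv(dv, file.path(out, "diversity_summary.csv"), row.names = FALSE)
cat("Diversity summary (g =", attr(dv, "rarefaction_g"), "):\n")
print(dv[c(1, nrow(dv) - 1, nrow(dv)), ], digits = 3)

lr <- locus_report(dataset)
write.csv(lr, file.path(out, "locus_report.csv"), row.names = FALSE)
cat("\nPIC ranges from", round(min(lr$pic), 2), "to", round(max(lr$pic), 2),
    "across", nrow(lr), "loci (mean", round(mean(lr$pic), 2), ").\n")

pl <- infer_ploidy(dataset, "group")
cat("\nInferred cytotypes:", paste(names(pl), pl, sep = "=",
                                   collapse = ", "), "\n")

# pairwise gametic disequilibrium between loci
loci <- dataset$loci$name
pairs <- t(combn(loci, 2))
ld <- data.frame(locusA = pairs[, 1], locusB = pairs[, 2],
                 p = apply(pairs, 1, function(pr)
                   suppressWarnings(ld_fisher(dataset, pr[1], pr[2])$p)))
ld$p_adj <- p.adjust(ld$p, "holm")
write.csv(ld, file.path(out, "gametic_disequilibrium.csv"),
          row.names = FALSE)
cat("\nGametic disequilibrium:", sum(ld$p_adj < 0.05), "of", nrow(ld),
    "locus pairs significant after Holm correction",
    "(loci simulated independently, so ~0 expected).\n")
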