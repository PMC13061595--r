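#!/usr/bin/env Rscript
# Stage 3 — covariate-adjusted fitness-EpiScore association scan.
#
# One OLS model per (trait, protein): EpiScore ~ trait_z + sex + age, with
# BH-FDR across all 5 x 109 = 545 tests.

suppressPackageStartupMessages(library(epirisk))

episcores <- read_matrix_csv("results/episcores.csv")
fitness <- read_fitness("results/synthetic/fitness.csv")
covariates <- read_covariates("results/synthetic/covariates.csv")

assoc <- association_scan(episcores, fitness, covariates, alpha = 0.05)
write.csv(as.data.frame(assoc), "results/associations.csv",
          row.names = FALSE, quote = FALSE)

sig <- assoc[assoc$significant_nominal, ]
cat(sprintf("Association scan: %d models, %d nominally significant (p < 0.05), %d after FDR\n",
            nrow(assoc), nrow(sig), sum(assoc$significant_fdr)))
print(table(sig$fitness_trait))
cat("strongest associations:\n")
print(head(sig[order(sig$p_value),
               c("fitness_trait", "protein_id", "beta", "p_value", "q_value")],
           5), row.names = FALSE)
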