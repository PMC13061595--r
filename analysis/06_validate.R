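#!/usr/bin/env Rscript
# Stage 6 — external CVD benchmark validation.
#
# Computes the 45-protein weighted CVD EpiScore per patient and its Spearman
# correlation with each disease risk score (BH-FDR across diseases), plus the
# descriptive Pearson matrices between fitness traits, covariates, CVD score
# and disease risks.

suppressPackageStartupMessages(library(epirisk))

episcores <- read_matrix_csv("results/episcores.csv")
risk_z <- read_matrix_csv("results/risk_z.csv")
fitness <- read_fitness("results/synthetic/fitness.csv")
covariates <- read_covariates("results/synthetic/covariates.csv")
cvd_w <- read_cvd_weights("results/synthetic/cvd_weights.csv")

episcores_std <- standardize_columns(episcores)
cvd <- compute_cvd_score(episcores_std, cvd_w)
risk <- list(z = risk_z)
class(risk) <- "risk_table"
bench <- validate_against_benchmark(risk, cvd, method = "spearman")
write.csv(bench, "results/benchmark.csv", row.names = FALSE, quote = FALSE)

traits <- setdiff(names(fitness), "sample_id")
desc <- cbind(as.matrix(fitness[traits]),
              age = covariates$age[match(fitness$sample_id,
                                         covariates$sample_id)],
              cvd_score = cvd[fitness$sample_id])
write.csv(round(pairwise_correlations(desc), 4),
          "results/correlation_matrix.csv", quote = FALSE)
write.csv(round(pairwise_correlations(as.matrix(fitness[traits]),
                                      risk_z[fitness$sample_id, ]), 4),
          "results/fitness_risk_correlations.csv", quote = FALSE)

cat("CVD benchmark validation (Spearman, BH-FDR):\n")
print(transform(bench, coefficient = round(coefficient, 3),
                q_value = signif(q_value, 3)), row.names = FALSE)
cat(sprintf("  diseases with FDR < 0.001: %d of %d\n",
            sum(bench$q_value < 0.001), nrow(bench)))
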