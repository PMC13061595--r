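#!/usr/bin/env Rscript
# Stage 2 — project CpG beta values onto protein EpiScores.
#
# Each EpiScore is the weighted sum of the sample's betas over the protein's
# CpG set, with reference-mean imputation for missing probes.

suppressPackageStartupMessages(library(epirisk))

in_dir <- "results/synthetic"
out_dir <- "results"
meth <- read_methylation(file.path(in_dir, "methylation.tsv"))
weights <- read_weights(file.path(in_dir, "weights.tsv"))
ref <- read_ref_means(file.path(in_dir, "ref_means.tsv"))

episcores <- project_episcores(meth, weights, ref)
write_matrix_csv(episcores, file.path(out_dir, "episcores.csv"))
rep <- attr(episcores, "imputation_report")
write.csv(rep, file.path(out_dir, "imputation_report.csv"),
          row.names = FALSE, quote = FALSE)

cat(sprintf("EpiScores: %d samples x %d proteins -> %s\n",
            nrow(episcores), ncol(episcores),
            file.path(out_dir, "episcores.csv")))
cat(sprintf("  imputed probes: %d; unreliable proteins: %d\n",
            sum(rep$n_imputed_probes), sum(rep$unreliable)))
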