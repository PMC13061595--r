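#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emulates the study's statistical structure: 290 participants (age ~
# truncated N(60, 11^2) on [33, 86], 52% female), five fitness traits with
# mild age/sex dependence, 109 protein EpiScores with 33 planted fitness
# effects, a methylation matrix consistent with the CpG-weight projector,
# a 10-disease log-hazard table and a 45-protein CVD benchmark panel.

suppressPackageStartupMessages(library(epirisk))

seed <- 1L
out_dir <- "results/synthetic"
spec <- cohort_spec(seed = seed)
study <- simulate_study(spec)
paths <- write_study(study, out_dir)

cat("Synthetic study written to", out_dir, "\n")
cat(sprintf("  samples: %d  (mean age %.1f, %.0f%% female)\n",
            nrow(study$covariates), mean(study$covariates$age),
            100 * mean(study$covariates$sex == 0)))
cat(sprintf("  proteins: %d x %d CpGs; planted effects: %d\n",
            spec$n_proteins, spec$cpgs_per_protein,
            sum(spec$effect_matrix != 0)))
cat(sprintf("  diseases: %d; CVD panel: %d proteins\n",
            spec$n_diseases, nrow(study$cvd_weights)))
cat(sprintf("  clipped beta entries: %d of %d (%.2f%%)\n",
            attr(study$methylation, "n_clipped"),
            length(study$methylation),
            100 * attr(study$methylation, "n_clipped") /
              length(study$methylation)))
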