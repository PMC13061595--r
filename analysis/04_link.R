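#!/usr/bin/env Rscript
# Stage 4 — link significant associations to EpiScore-disease hazards and
# assess direction consistency along the fitness -> EpiScore -> disease
# chain against the expected trait directions (BMI risk-increasing, the
# rest protective).

suppressPackageStartupMessages(library(epirisk))

assoc <- read.csv("results/associations.csv", stringsAsFactors = FALSE)
hazards <- read_hazards("results/synthetic/hazards.csv")

sig <- assoc[assoc$significant_nominal, ]
links <- link_fitness_disease(sig, hazards)
res <- assess_direction_consistency(links)
write.csv(res$links, "results/links.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("Linkage: %d significant pairs x hazard table -> %d (trait, protein, disease) links\n",
            nrow(sig), res$n_links))
cat(sprintf("  direction-consistent: %d of %d (%.0f%%)\n",
            res$consistent_count, res$n_links,
            100 * res$consistent_count / max(res$n_links, 1)))
cat(sprintf("  distinct (trait, disease) pairs: %d (%d with a consistent chain)\n",
            nrow(res$pair_counts), sum(res$pair_counts$any_consistent)))
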