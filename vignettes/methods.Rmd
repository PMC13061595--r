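---
title: "Fitness-mediated epigenetic disease risk scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness-mediated epigenetic disease risk scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirisk)
```

## The scientific problem

DNA methylation profiles can be projected onto estimates of circulating
plasma protein levels ("EpiScores"): each protein has a published set of CpG
weights, and the score is a weighted linear combination of the sample's beta
values at those CpGs. Because many EpiScores carry published associations
with incident disease (Cox log hazard ratios), they offer a molecular route
from modifiable exposures — here, physical and cognitive fitness — to
disease risk. `epirisk` implements that route end to end:

1. **Projection.** `score(s, p) = Σ_k w_k β_k(s)` over protein `p`'s CpG
   set, with reference-mean imputation for missing probes.
2. **Association scan.** One OLS model per (fitness trait, protein):
   `EpiScore ~ trait_z + sex + age`, with the trait cohort z-scored, sex
   coded female = 0 / male = 1, and age in years. Nominal significance at
   p < 0.05 and Benjamini–Hochberg FDR across all trait × protein tests.
3. **Linkage.** Significant (trait, protein) pairs are joined to an external
   EpiScore–disease log-hazard table on the protein, giving
   (trait, protein, disease) chains whose net direction is
   `sign(β) · sign(log HR)`, compared against each trait's expected risk
   direction (BMI risk-increasing; VO₂max, grip strength, jump performance
   and cognition protective).
4. **Composite risk.** Per patient and disease,
   `raw = Σ_i logHR_i · EpiScore_i^std + Σ_{(i,j)} β_{i→j} · logHR_i · Fitness_j^z`
   — a direct polygenic-score-style term over standardized EpiScores plus an
   indirect product-of-coefficients term propagating fitness effects through
   the EpiScore–disease hazards. Raw scores are z-scored per disease across
   the cohort; `z > 1.28` (≈ the 90th percentile of a normal) flags the top
   decile as high-risk.
5. **Categorization and ranking.** Fitness values are labelled low / normal
   / high against mean ± 1.28 SD boundaries within (age-decade × sex)
   strata (cognition instead uses cohort-wide 10th/90th empirical
   percentiles), and patients are ranked by their number of flagged
   diseases.
6. **External validation.** An independently weighted 45-protein CVD
   EpiScore (`Σ weight_i · EpiScore_i`) is correlated (Spearman, BH-FDR
   across diseases) with every disease risk score as a convergent-validity
   benchmark.

The hazard ratios and CVD weights are *inputs*, not estimates: the package
deliberately does not fit survival models.

## Model assumptions, made explicit

- **Projection is a plain weighted sum.** No intercept and no beta
  standardization before weighting; the imputation policy (reference mean)
  means a fully missing sample scores the population baseline `Σ w·ref`.
  Proteins whose imputed fraction exceeds `max_impute_fraction` (default
  0.2) are flagged unreliable rather than dropped.
- **The indirect term indexes the log HR by the chain's protein.** Written
  out, a chain is (trait j) → (protein i) → (disease d), and the term is
  `β_{i→j} · logHR_i(d) · fitness_z(j)`: fitness effects are propagated
  through the EpiScore–disease hazard of the mediating protein. Only
  nominally significant (p < 0.05) pairs enter the indirect sum by default.
- **Both terms are retained when a protein contributes to both.** The
  composite equation is a sum; no double-counting correction is applied.
- **Strict inequality for flags, closed band for categories.** A risk
  z-score exactly at 1.28 is *not* flagged ("exceeding" is strict); a
  fitness value exactly on a category boundary is "normal".
- **Sample SD everywhere.** All z-scoring uses the n − 1 denominator; this
  is a consistency choice (the convention is immaterial as long as it is
  uniform, and it matches `stats::sd`).
- **Two-sided t tests.** Coefficient p-values are two-sided on the residual
  degrees of freedom, the standard choice for OLS coefficients.
- **BH family.** FDR correction is applied jointly across all trait ×
  protein tests (the conservative reading); `fdr_family = "per-trait"`
  switches to within-trait adjustment.
- **Spearman by default for benchmark validation**, since rank correlations
  are what the validation reports; Pearson is available via `method =
  "pearson"`. Note the benchmark correlates identically on raw and z-scored
  risk because the per-disease z transform is monotone.

## The synthetic study generator

There is no bundled cohort: `simulate_study()` manufactures one whose
statistical structure matches the study conditions the pipeline targets,
so every stage is testable without any download.

- **Demographics.** n = 290; age from a normal with mean 60 and SD 11,
  truncated to [33, 86] by rejection sampling (the simplest distribution
  consistent with a stated mean/SD/range; truncation pulls the mean to
  ≈ 59.95, which the calibration checks account for); sex Bernoulli with
  52% female, coded female = 0 / male = 1.
- **Fitness traits** are generated on natural scales with configurable
  means, SDs and mild age/sex slopes (`default_fitness_params()`); the
  defaults (e.g., VO₂max ≈ N(35, 7²) mL·kg⁻¹·min⁻¹ declining ~0.3/year,
  BMI ≈ N(26, 4²) kg/m²) are physiologically plausible placeholders —
  the pipeline z-scores traits before modeling, so only their relative
  structure propagates.
- **Planted effects.** Latent EpiScores follow
  `α + Σ_j β_j · fitness_z(j) + γ_age (age − 60) + γ_sex sex + ε`,
  `ε ~ N(0, 0.5²)`. Effects are planted on the *cohort z-scored* fitness —
  the same scale the association scan models on — so the scan's estimand
  equals the planted coefficient exactly, which is what makes the
  confidence-interval coverage checks clean. The default effect matrix has
  33 nonzero entries (BMI 18 positive; JumpMax 6, GripStrength 5, Cognition
  4 negative; VO₂max none) of magnitude 0.35, a fixed deterministic layout
  mirroring the association pattern the pipeline is designed to detect.
- **Projector-consistent methylation.** Each protein gets a disjoint block
  of 20 CpGs with weights of magnitude 0.1–1 and reference means in
  (0.1, 0.9). Betas are embedded as the minimum-norm perturbation of the
  reference profile achieving `w·β = s` (per protein:
  `β = ref + w (s − w·ref)/‖w‖²`), then clipped to [0, 1] because betas are
  proportions. `simulate_study()` anchors each protein's latent intercept at
  its projector baseline `w·ref`, which keeps clipping to a fraction of a
  percent of entries; clipped entries are counted and identified so
  round-trip checks can target the exact entries that recover
  (projection equals latent to < 1e−8 on unclipped entries).
- **External tables.** Hazard log HRs ~ N(0, 0.2²) over 8 proteins per
  disease (effect-carrying proteins preferentially included so indirect
  chains exist); the CVD panel draws 45 proteins with N(0, 0.2²) weights.

**What the generator does *not* emulate:** genome-wide methylation (only
projector CpGs are generated), shared CpGs between proteins, array batch
effects, missing-data patterns, correlated disease hazards, and — by
default — any overlap structure between the CVD panel and the hazard table.
Consequently, passing tests demonstrate the pipeline's *mechanics and
statistical calibration* (type-I error, CI coverage, flag rates,
round-trip fidelity), not the cohort-specific effect sizes or the strongly
positive CVD benchmark correlations a real cohort exhibits; those depend on
real shared biology the generator only reproduces when a shared-weight
overlap is explicitly constructed (as one validation test does).

## Numerical choices

- OLS via QR (`lm.fit`-grade decomposition) with all responses sharing one
  decomposition per trait; rank deficiency is an error naming the collinear
  columns, not a silent drop.
- BH via `stats::p.adjust`; Spearman rho via `stats::cor` on mid-ranks with
  the t approximation on n − 2 df for p-values (|rho| = 1 maps to p = 0).
- Empirical percentiles use type-7 (linear interpolation) quantiles.
- Ranking ties break by total z-score, then sample ID, making reports
  reproducible.
- Degenerate inputs fail loudly: constant columns (z-scoring), zero-norm
  weight vectors (embedding), unresolvable probes (projection), misaligned
  sample IDs (every join).
- Tables are written as plain CSV/TSV at full numeric precision
  (~15 significant digits), so write-then-read round-trips values and
  reruns under an identical configuration are byte-identical.
- Age strata that are empty, singleton or zero-variance fall back to
  cohort-wide thresholds with a warning; age bins extend automatically to
  cover the observed range.

## Problem sizes used in the checks

The test-suite simulations are sized for tight Monte-Carlo tolerances at
interactive runtimes: flag-rate and category-band laws at n = 100,000
(binomial SE < 0.1%); demographic calibration at n = 100,000; CI coverage
over 200 replicate cohorts of n = 290 (two planted effects each); type-I
error over 50 replicates × 1,000 null tests (50,000 tests, SE ≈ 0.1%);
oracle equivalence over 100 random small designs.

## Known limitations

- Risk scores are cohort-relative rankings, not calibrated absolute risks;
  a z-score of 1.28 means "top decile of this cohort", nothing more.
- Hazard ratios are transported from external populations without
  re-estimation; population mismatch propagates directly into the scores.
- The projection implements the plain weighted sum; if an upstream scoring
  tool applies an intercept or pre-standardizes betas, its scores will
  differ by an affine transform (harmless to the scan and to Spearman
  validation, but not to raw score values).
- Overlapping CpG sets between proteins are unsupported in the *generator*
  (the projector itself handles them fine); the disjoint-block choice keeps
  the embedding solvable in closed form.
- The name harmonizer resolves duplicates by suffixing; choosing between
  platform duplicates (e.g., two epitope variants of one protein) is left
  to the analyst.
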