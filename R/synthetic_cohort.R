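#' Specification of a synthetic study cohort
#'
#' Bundles every parameter of the synthetic study generator: cohort
#' demographics, fitness-trait distributions, the planted fitness->EpiScore
#' effect matrix, projector geometry (proteins and CpGs per protein), and the
#' sizes of the external hazard and CVD weight tables. Defaults emulate the
#' study cohort the pipeline was designed around: 290 participants, age
#' 60 +/- 11 years truncated to 33-86, 52% female, 109 protein EpiScores,
#' 10 diseases and a 45-protein CVD benchmark.
#'
#' @param n_samples Number of participants.
#' @param age_mean,age_sd Mean and SD (years) of the underlying normal age
#'   distribution before truncation.
#' @param age_range Length-2 numeric, inclusive truncation bounds in years.
#' @param female_fraction Expected proportion of female participants
#'   (sex is coded female = 0, male = 1).
#' @param n_proteins Number of protein EpiScores.
#' @param cpgs_per_protein CpGs in each protein's weight set (disjoint sets).
#' @param n_diseases Number of diseases in the hazard table.
#' @param n_cvd_proteins Number of entries in the CVD benchmark weight table.
#' @param effect_matrix Numeric matrix, 5 x `n_proteins` (rows = fitness
#'   traits in the order VO2max, GripStrength, JumpMax, BMI, Cognition):
#'   planted coefficients on cohort z-scored fitness. Defaults to a sparse
#'   matrix with 33 nonzero entries (18 positive for BMI; 6, 5 and 4 negative
#'   for JumpMax, GripStrength and Cognition; none for VO2max).
#' @param noise_sd Residual SD of the latent EpiScore model.
#' @param age_slope,sex_slope Covariate effects (per year of age, and for
#'   male vs female) on every latent EpiScore, giving the confounding the
#'   association scan must adjust away.
#' @param fitness_params Data frame of per-trait generation parameters
#'   (columns `trait`, `mean`, `sd`, `age_slope`, `sex_slope`); see
#'   [default_fitness_params()].
#' @param hazard_log_hr_sd SD of the N(0, sd^2) draw for log hazard ratios.
#' @param proteins_per_disease Number of proteins linked to each disease in
#'   the synthetic hazard table.
#' @param seed Integer seed; all generator functions are deterministic in it.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_samples = 290L,
                        age_mean = 60, age_sd = 11, age_range = c(33, 86),
                        female_fraction = 0.52,
                        n_proteins = 109L, cpgs_per_protein = 20L,
                        n_diseases = 10L, n_cvd_proteins = 45L,
                        effect_matrix = default_effect_matrix(n_proteins),
                        noise_sd = 0.5,
                        age_slope = 0.01, sex_slope = 0.2,
                        fitness_params = default_fitness_params(),
                        hazard_log_hr_sd = 0.2,
                        proteins_per_disease = 8L,
                        seed = 1L) {
  spec <- list(
    n_samples = as.integer(n_samples),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    female_fraction = female_fraction,
    n_proteins = as.integer(n_proteins),
    cpgs_per_protein = as.integer(cpgs_per_protein),
    n_diseases = as.integer(n_diseases),
    n_cvd_proteins = as.integer(n_cvd_proteins),
    effect_matrix = effect_matrix,
    noise_sd = noise_sd,
    age_slope = age_slope, sex_slope = sex_slope,
    fitness_params = fitness_params,
    hazard_log_hr_sd = hazard_log_hr_sd,
    proteins_per_disease = as.integer(proteins_per_disease),
    seed = as.integer(seed)
  )
  if (spec$n_samples < 2L)
    stop("cohort_spec: n_samples must be >= 2", call. = FALSE)
  if (!(female_fraction > 0 && female_fraction < 1))
    stop("cohort_spec: female_fraction must be in (0, 1)", call. = FALSE)
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("cohort_spec: age_range must be an increasing pair", call. = FALSE)
  if (noise_sd <= 0)
    stop("cohort_spec: noise_sd must be > 0", call. = FALSE)
  if (spec$n_cvd_proteins > spec$n_proteins)
    stop("cohort_spec: n_cvd_proteins cannot exceed n_proteins", call. = FALSE)
  if (spec$cpgs_per_protein < 1L)
    stop("cohort_spec: cpgs_per_protein must be >= 1", call. = FALSE)
  if (!is.matrix(spec$effect_matrix) ||
      nrow(spec$effect_matrix) != length(fitness_traits()) ||
      ncol(spec$effect_matrix) != spec$n_proteins)
    stop("cohort_spec: effect_matrix must be ", length(fitness_traits()),
         " x n_proteins", call. = FALSE)
  class(spec) <- "cohort_spec"
  spec
}

#' Fitness trait names, in canonical order
#'
#' @return Character vector of the five trait identifiers.
#' @export
fitness_traits <- function() {
  c("vo2max", "grip_strength", "jump_max", "bmi", "cognition")
}

#' Default planted fitness->EpiScore effect matrix
#'
#' A sparse 5 x `n_proteins` matrix with 33 nonzero coefficients: 18 positive
#' BMI effects, 6 negative JumpMax, 5 negative GripStrength and 4 negative
#' Cognition effects, none for VO2max, each on a distinct protein. The layout
#' mirrors the association pattern the pipeline is built to detect (BMI the
#' dominant, risk-increasing trait; strength, power and cognition protective;
#' aerobic capacity silent). Deterministic: no random draw is involved.
#'
#' @param n_proteins Number of protein columns (>= 33 for the full default).
#' @param magnitude Absolute value of each planted coefficient.
#' @return A 5 x `n_proteins` matrix with trait row names.
#' @export
default_effect_matrix <- function(n_proteins = 109L, magnitude = 0.35) {
  traits <- fitness_traits()
  em <- matrix(0, nrow = length(traits), ncol = n_proteins,
               dimnames = list(traits, protein_ids(n_proteins)))
  plan <- list(bmi = c(18L, +1), jump_max = c(6L, -1),
               grip_strength = c(5L, -1), cognition = c(4L, -1))
  col <- 1L
  for (tr in names(plan)) {
    k <- plan[[tr]][1]
    if (col > n_proteins) break
    idx <- seq.int(col, min(col + k - 1L, n_proteins))
    em[tr, idx] <- plan[[tr]][2] * magnitude
    col <- col + k
  }
  em
}

#' Default fitness-trait generation parameters
#'
#' Natural-scale means and SDs for the five traits, with mild age and sex
#' dependence. These are configurable placeholders chosen to be physiologically
#' plausible for a mostly-older adult cohort (e.g., VO2max ~ 35 mL/kg/min
#' declining with age, BMI ~ 26 kg/m2 rising slightly with age); the pipeline
#' z-scores traits before any modeling so only their relative structure
#' matters downstream.
#'
#' @return Data frame with columns `trait`, `mean`, `sd`, `age_slope`
#'   (units per year, applied to age centered at the cohort age mean) and
#'   `sex_slope` (male minus female shift).
#' @export
default_fitness_params <- function() {
  data.frame(
    trait = fitness_traits(),
    mean = c(35, 0.45, 0.20, 26, 6),
    sd = c(7, 0.10, 0.05, 4, 1.5),
    age_slope = c(-0.30, -0.002, -0.001, 0.05, -0.02),
    sex_slope = c(5, 0.08, 0.03, 0.5, 0),
    stringsAsFactors = FALSE
  )
}

protein_ids <- function(n) sprintf("prot_%03d", seq_len(n))
sample_ids <- function(n) sprintf("S%04d", seq_len(n))
disease_ids <- function(n) sprintf("disease_%02d", seq_len(n))

#' Draw from a truncated normal by rejection sampling
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the untruncated normal.
#' @param lower,upper Inclusive truncation bounds.
#' @return Numeric vector of length `n` within `[lower, upper]`.
#' @keywords internal
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    # acceptance rate here is ~0.98; a single refill pass almost always suffices
    draw <- stats::rnorm(max(n - length(out), 16L) * 2L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort: covariates, fitness and latent EpiScores
#'
#' Draws ages from a truncated normal, sex from a Bernoulli, fitness traits
#' from per-trait normal models with mild age/sex dependence, and latent
#' EpiScores from the planted linear model
#' `score = alpha + sum_j beta[j] * fitness_z[j] + age_slope*(age - age_mean) +
#' sex_slope*sex + N(0, noise_sd^2)`, where `fitness_z` is the cohort
#' z-scored fitness matrix (the same scale the association scan models on)
#' and `alpha` is 0 for every protein ([simulate_study()] re-anchors each
#' protein at its projector baseline before embedding). Age is centered at
#' `age_mean` so covariate confounding perturbs scores around zero.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `covariates` (data frame: `sample_id`, `age`,
#'   `sex` coded female = 0 / male = 1), `fitness` (data frame: `sample_id`
#'   plus the five traits on natural scales) and `latent` (matrix
#'   samples x proteins of ground-truth EpiScores).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  ids <- sample_ids(n)

  age <- rtruncnorm_reject(n, spec$age_mean, spec$age_sd,
                           spec$age_range[1], spec$age_range[2])
  sex <- stats::rbinom(n, 1L, 1 - spec$female_fraction)  # male = 1

  fp <- spec$fitness_params
  fitness <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fp))) {
    fitness[[fp$trait[i]]] <- fp$mean[i] +
      fp$age_slope[i] * (age - spec$age_mean) +
      fp$sex_slope[i] * sex +
      stats::rnorm(n, 0, fp$sd[i])
  }

  fz <- scale(as.matrix(fitness[fitness_traits()]))
  latent <- fz %*% spec$effect_matrix +
    spec$age_slope * (age - spec$age_mean) + spec$sex_slope * sex +
    matrix(stats::rnorm(n * spec$n_proteins, 0, spec$noise_sd),
           nrow = n, ncol = spec$n_proteins)
  dimnames(latent) <- list(ids, protein_ids(spec$n_proteins))

  list(
    covariates = data.frame(sample_id = ids, age = age, sex = sex,
                            stringsAsFactors = FALSE),
    fitness = fitness,
    latent = latent
  )
}

#' Generate per-protein CpG weight sets and reference mean betas
#'
#' Each protein receives a disjoint block of `cpgs_per_protein` CpGs with
#' nonzero weights (|w| uniform in 0.1-1, random sign) and reference
#' population mean betas uniform in (0.1, 0.9).
#'
#' @param spec A [cohort_spec()].
#' @return List with `weights` (data frame: `protein_id`, `cpg_id`, `weight`)
#'   and `ref_means` (named numeric vector, CpG -> mean beta).
#' @export
generate_weight_sets <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$cpgs_per_protein < 1L)
    stop("generate_weight_sets: cpgs_per_protein must be >= 1", call. = FALSE)
  set.seed(spec$seed + 1L)
  n_cpg <- spec$n_proteins * spec$cpgs_per_protein
  cpgs <- sprintf("cg%08d", seq_len(n_cpg))
  w <- stats::runif(n_cpg, 0.1, 1) * sample(c(-1, 1), n_cpg, replace = TRUE)
  weights <- data.frame(
    protein_id = rep(protein_ids(spec$n_proteins), each = spec$cpgs_per_protein),
    cpg_id = cpgs,
    weight = w,
    stringsAsFactors = FALSE
  )
  ref <- stats::runif(n_cpg, 0.1, 0.9)
  names(ref) <- cpgs
  list(weights = weights, ref_means = ref)
}

#' Embed latent EpiScores into a projection-consistent methylation matrix
#'
#' Constructs beta values such that the weighted-sum projector recovers each
#' latent score. For protein `i` with weight vector `w` and reference means
#' `b`, a sample with latent score `s` receives betas
#' `b + w * (s - w.b) / (w.w)` on that protein's CpGs — the minimum-norm
#' perturbation of the reference profile achieving `w.beta = s`. Values are
#' then clipped to `[0, 1]` (betas are proportions); clipped entries break the
#' exact round trip and are counted and reported via a warning.
#'
#' @param latent Matrix samples x proteins of latent scores.
#' @param weights Weight data frame as from [generate_weight_sets()].
#' @param ref_means Named numeric vector of reference mean betas.
#' @return Matrix of betas, CpGs as rows and samples as columns (the
#'   transposed layout the projector reads), with attributes `n_clipped`
#'   (number of clipped beta entries) and `clipped` (logical samples x
#'   proteins matrix marking score entries whose CpG block was clipped and
#'   will therefore not round-trip exactly).
#' @export
embed_methylation <- function(latent, weights, ref_means) {
  proteins <- colnames(latent)
  missing_w <- setdiff(proteins, unique(weights$protein_id))
  if (length(missing_w))
    stop("embed_methylation: no weight set for ",
         paste(missing_w, collapse = ", "), call. = FALSE)

  wsplit <- split(weights[c("cpg_id", "weight")], weights$protein_id)
  n_cpg_total <- sum(vapply(wsplit[proteins], nrow, 1L))
  beta <- matrix(NA_real_, nrow = n_cpg_total, ncol = nrow(latent))
  colnames(beta) <- rownames(latent)
  rn <- character(n_cpg_total)
  n_clipped <- 0L
  clip_mat <- matrix(FALSE, nrow = nrow(latent), ncol = length(proteins),
                     dimnames = dimnames(latent))
  row0 <- 0L
  for (p in proteins) {
    ws <- wsplit[[p]]
    w <- ws$weight
    wnorm2 <- sum(w * w)
    if (wnorm2 == 0)
      stop("embed_methylation: zero-norm weight vector for ", p, call. = FALSE)
    b <- ref_means[ws$cpg_id]
    if (anyNA(b))
      stop("embed_methylation: reference means missing for CpGs of ", p,
           call. = FALSE)
    baseline <- sum(w * b)
    # outer: each sample's betas = b + w * (s - baseline) / |w|^2
    block <- b + outer(w / wnorm2, latent[, p] - baseline)
    clipped <- block < 0 | block > 1
    n_clipped <- n_clipped + sum(clipped)
    clip_mat[, p] <- colSums(clipped) > 0L
    block[block < 0] <- 0
    block[block > 1] <- 1
    idx <- row0 + seq_along(w)
    beta[idx, ] <- block
    rn[idx] <- ws$cpg_id
    row0 <- row0 + length(w)
  }
  rownames(beta) <- rn
  if (n_clipped > 0L)
    warning("embed_methylation: ", n_clipped,
            " beta value(s) clipped to [0, 1]; projection will not recover",
            " the latent score exactly for the affected samples",
            call. = FALSE)
  attr(beta, "n_clipped") <- n_clipped
  attr(beta, "clipped") <- clip_mat
  beta
}

#' Generate a synthetic EpiScore-disease hazard table
#'
#' Each disease is linked to a random subset of proteins with log hazard
#' ratios drawn from N(0, `hazard_log_hr_sd`^2). Proteins carrying planted
#' fitness effects are preferentially included so that indirect risk chains
#' exist by construction.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `disease`, `protein_id`, `log_hr`;
#'   (disease, protein) pairs unique.
#' @export
generate_hazard_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 2L)
  prot <- protein_ids(spec$n_proteins)
  effect_prots <- prot[colSums(spec$effect_matrix != 0) > 0]
  k <- min(spec$proteins_per_disease, spec$n_proteins)
  rows <- lapply(disease_ids(spec$n_diseases), function(d) {
    n_eff <- min(length(effect_prots), max(1L, k %/% 2L))
    chosen <- c(sample(effect_prots, n_eff),
                sample(setdiff(prot, effect_prots), k - n_eff))
    data.frame(disease = d, protein_id = chosen,
               log_hr = stats::rnorm(k, 0, spec$hazard_log_hr_sd),
               stringsAsFactors = FALSE)
  })
  hz <- do.call(rbind, rows)
  rownames(hz) <- NULL
  hz
}

#' Generate a synthetic CVD benchmark weight table
#'
#' Draws `n_cvd_proteins` proteins (without replacement) and assigns each a
#' weight from N(0, 0.2^2), emulating an externally published 45-protein
#' cardiovascular EpiScore.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `protein_id`, `weight`.
#' @export
generate_cvd_weights <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_cvd_proteins > spec$n_proteins)
    stop("generate_cvd_weights: n_cvd_proteins exceeds n_proteins",
         call. = FALSE)
  set.seed(spec$seed + 3L)
  data.frame(
    protein_id = sort(sample(protein_ids(spec$n_proteins),
                             spec$n_cvd_proteins)),
    weight = stats::rnorm(spec$n_cvd_proteins, 0, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper running every generator under one spec: cohort,
#' weight sets, projection-consistent methylation matrix, hazard table and
#' CVD benchmark weights. Each protein's latent intercept is set to its
#' projector baseline (the weighted sum of reference mean betas), so embedded
#' beta values center on the reference means and clipping stays rare; the
#' returned `latent` matrix is on this anchored scale, the one the projection
#' recovers.
#'
#' @param spec A [cohort_spec()].
#' @return List with `covariates`, `fitness`, `latent`, `weights`,
#'   `ref_means`, `methylation` (CpGs x samples), `hazards`, `cvd_weights`
#'   and the `spec` itself.
#' @export
simulate_study <- function(spec = cohort_spec()) {
  cohort <- generate_cohort(spec)
  ws <- generate_weight_sets(spec)
  baseline <- vapply(split(ws$weights, ws$weights$protein_id), function(d) {
    sum(d$weight * ws$ref_means[d$cpg_id])
  }, numeric(1))[colnames(cohort$latent)]
  cohort$latent <- sweep(cohort$latent, 2L, baseline, `+`)
  meth <- embed_methylation(cohort$latent, ws$weights, ws$ref_means)
  c(cohort,
    list(weights = ws$weights, ref_means = ws$ref_means,
         methylation = meth,
         hazards = generate_hazard_table(spec),
         cvd_weights = generate_cvd_weights(spec),
         spec = spec))
}
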