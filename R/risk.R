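#' Threshold configuration for flagging and categorization
#'
#' @param z_flag_threshold Risk z-score above which a patient is flagged
#'   high-risk (default 1.28, approximately the 90th percentile of a
#'   standard normal; flags use strict `>`).
#' @param fitness_sd_threshold Half-width, in SDs, of the "normal" band for
#'   the SD-categorized traits (default 1.28).
#' @param cognition_percentiles Lower/upper empirical percentiles bounding
#'   "normal" cognition (default `c(10, 90)`).
#' @param age_bins Breaks (years) of the age strata used for fitness
#'   categorization; default decades 30-90.
#' @param stratify_by_sex Whether categorization strata cross age bins with
#'   sex (default `TRUE`).
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(z_flag_threshold = 1.28,
                             fitness_sd_threshold = 1.28,
                             cognition_percentiles = c(10, 90),
                             age_bins = seq(30, 90, by = 10),
                             stratify_by_sex = TRUE) {
  if (z_flag_threshold <= 0 || fitness_sd_threshold <= 0)
    stop("threshold_config: thresholds must be positive", call. = FALSE)
  if (length(cognition_percentiles) != 2L ||
      any(cognition_percentiles <= 0) || any(cognition_percentiles >= 100) ||
      cognition_percentiles[1] >= cognition_percentiles[2])
    stop("threshold_config: cognition percentiles must be an increasing ",
         "pair inside (0, 100)", call. = FALSE)
  structure(list(z_flag_threshold = z_flag_threshold,
                 fitness_sd_threshold = fitness_sd_threshold,
                 cognition_percentiles = cognition_percentiles,
                 age_bins = age_bins,
                 stratify_by_sex = stratify_by_sex),
            class = "threshold_config")
}

hazard_weight_matrix <- function(hazards, proteins) {
  diseases <- unique(hazards$disease)
  Wh <- matrix(0, nrow = length(proteins), ncol = length(diseases),
               dimnames = list(proteins, diseases))
  keep <- hazards$protein_id %in% proteins
  if (!all(keep)) {
    lost <- unique(hazards$protein_id[!keep])
    warning("hazard table protein(s) absent from the EpiScore matrix, ",
            "skipped: ", paste(utils::head(lost, 5L), collapse = ", "),
            call. = FALSE)
  }
  hz <- hazards[keep, , drop = FALSE]
  Wh[cbind(match(hz$protein_id, proteins), match(hz$disease, diseases))] <-
    hz$log_hr
  empty <- !(diseases %in% hz$disease)
  if (any(empty))
    warning("no scoring proteins for disease(s): ",
            paste(diseases[empty], collapse = ", "), "; scores set to 0",
            call. = FALSE)
  Wh
}

#' Direct per-disease risk term
#'
#' `direct(s, d) = sum_i log_hr(i, d) * episcore_std(s, i)` over the
#' proteins the hazard table links to disease `d` — a polygenic-score-style
#' weighted sum of standardized EpiScores with log hazard ratios as weights.
#'
#' @param episcores_std Standardized EpiScore matrix (samples x proteins).
#' @param hazards Hazard table (`disease`, `protein_id`, `log_hr`).
#' @return Matrix samples x diseases.
#' @export
compute_direct_risk <- function(episcores_std, hazards) {
  Wh <- hazard_weight_matrix(hazards, colnames(episcores_std))
  episcores_std %*% Wh
}

#' Indirect (fitness-mediated) per-disease risk term
#'
#' Product-of-coefficients chains: for each significant fitness->EpiScore
#' association (trait j, protein i, coefficient beta) and each disease d the
#' hazard table links protein i to,
#' `indirect(s, d) += beta * log_hr(i, d) * fitness_z(s, j)`. The log HR is
#' the one of the chain's EpiScore for the target disease, so fitness effects
#' are propagated through the EpiScore-disease hazards.
#'
#' @param fitness_std Z-scored fitness matrix (samples x traits, with sample
#'   rownames).
#' @param sig Significant association rows (`fitness_trait`, `protein_id`,
#'   `beta`).
#' @param hazards Hazard table (`disease`, `protein_id`, `log_hr`).
#' @return Matrix samples x diseases (all diseases of `hazards`, zero
#'   columns where no chain reaches a disease, with a warning).
#' @export
compute_indirect_risk <- function(fitness_std, sig, hazards) {
  diseases <- unique(hazards$disease)
  traits <- colnames(fitness_std)
  chains <- merge(sig[c("fitness_trait", "protein_id", "beta")],
                  hazards, by = "protein_id")
  # per-disease coefficient on each trait: sum over chains of beta * log_hr
  C <- matrix(0, nrow = length(traits), ncol = length(diseases),
              dimnames = list(traits, diseases))
  if (nrow(chains)) {
    miss <- setdiff(unique(chains$fitness_trait), traits)
    if (length(miss))
      stop("compute_indirect_risk: trait(s) missing from fitness matrix: ",
           paste(miss, collapse = ", "), call. = FALSE)
    agg <- stats::aggregate(beta_loghr ~ fitness_trait + disease,
                            data = transform(chains,
                                             beta_loghr = beta * log_hr),
                            FUN = sum)
    C[cbind(match(agg$fitness_trait, traits),
            match(agg$disease, diseases))] <- agg$beta_loghr
  }
  empty <- !(diseases %in% chains$disease)
  if (any(empty))
    warning("compute_indirect_risk: no chain reaches disease(s): ",
            paste(diseases[empty], collapse = ", "), "; term is 0",
            call. = FALSE)
  fitness_std %*% C
}

#' Combine risk terms, normalize and flag high-risk patients
#'
#' Raw score = direct + indirect; each disease column is then z-scored
#' across the cohort (sample SD) and patients with `z >` the flag threshold
#' are marked high-risk — with the default 1.28 this targets roughly the top
#' decile of the cohort's risk distribution.
#'
#' @param direct,indirect Matrices samples x diseases (aligned; `indirect`
#'   may be `NULL` or 0 for a direct-only score).
#' @param config A [threshold_config()].
#' @return List of class `risk_table` with matrices `raw`, `z`, `high_risk`
#'   and the threshold used.
#' @export
compute_risk_scores <- function(direct, indirect = NULL,
                                config = threshold_config()) {
  raw <- if (is.null(indirect)) direct else {
    if (!identical(dim(direct), dim(indirect)))
      stop("compute_risk_scores: direct and indirect terms are not aligned",
           call. = FALSE)
    if (!is.null(colnames(indirect)) &&
        !identical(colnames(direct), colnames(indirect)))
      indirect <- indirect[, colnames(direct), drop = FALSE]
    direct + indirect
  }
  z <- standardize_columns(raw)
  structure(list(raw = raw,
                 z = z,
                 high_risk = z > config$z_flag_threshold,
                 z_flag_threshold = config$z_flag_threshold),
            class = "risk_table")
}

categorize_numeric <- function(x, lower, upper) {
  # boundary values (exactly at a threshold) are "normal"
  out <- rep("normal", length(x))
  out[x < lower] <- "low"
  out[x > upper] <- "high"
  out
}

#' Categorize fitness values as low / normal / high
#'
#' VO2max, GripStrength, JumpMax and BMI are categorized against
#' mean +/- `fitness_sd_threshold` * SD boundaries computed within
#' (age-bin x sex) strata; Cognition against cohort-wide empirical
#' percentiles (linear interpolation between order statistics). Values
#' exactly on a boundary are "normal". Strata with fewer than 2 samples or
#' zero variance fall back to cohort-wide boundaries with a warning.
#'
#' @param fitness Data frame with `sample_id` and trait columns on natural
#'   scales.
#' @param covariates Data frame with `sample_id`, `age`, `sex`.
#' @param config A [threshold_config()].
#' @return Data frame with `sample_id`, `group_id` (stratum label) and one
#'   category column per trait.
#' @export
categorize_fitness <- function(fitness, covariates,
                               config = threshold_config()) {
  ids <- fitness$sample_id
  covariates <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
  if (anyNA(covariates$age))
    stop("categorize_fitness: covariates missing for some samples",
         call. = FALSE)
  bins <- config$age_bins
  if (min(covariates$age) < min(bins) || max(covariates$age) > max(bins))
    bins <- sort(unique(c(floor(min(covariates$age) / 10) * 10, bins,
                          ceiling(max(covariates$age) / 10) * 10)))
  age_bin <- cut(covariates$age, breaks = bins, include.lowest = TRUE,
                 right = FALSE)
  group <- if (config$stratify_by_sex) {
    interaction(age_bin, ifelse(covariates$sex == 0, "F", "M"), drop = TRUE)
  } else age_bin
  group <- droplevels(group)

  sd_traits <- intersect(c("vo2max", "grip_strength", "jump_max", "bmi"),
                         names(fitness))
  pct_traits <- intersect("cognition", names(fitness))
  out <- data.frame(sample_id = ids, group_id = as.character(group),
                    stringsAsFactors = FALSE)
  k <- config$fitness_sd_threshold
  fell_back <- character(0)
  for (tr in sd_traits) {
    x <- fitness[[tr]]
    cat_tr <- rep(NA_character_, length(x))
    for (g in levels(group)) {
      at <- group == g
      m <- mean(x[at]); s <- stats::sd(x[at])
      if (sum(at) < 2L || !is.finite(s) || s == 0) {
        m <- mean(x); s <- stats::sd(x)
        fell_back <- union(fell_back, g)
      }
      cat_tr[at] <- categorize_numeric(x[at], m - k * s, m + k * s)
    }
    out[[tr]] <- cat_tr
  }
  for (tr in pct_traits) {
    x <- fitness[[tr]]
    q <- stats::quantile(x, probs = config$cognition_percentiles / 100,
                         names = FALSE, type = 7)
    out[[tr]] <- categorize_numeric(x, q[1], q[2])
  }
  if (length(fell_back))
    warning("categorize_fitness: stratum/strata too small or degenerate, ",
            "cohort-wide thresholds used: ",
            paste(fell_back, collapse = ", "), call. = FALSE)
  out
}

#' Rank patients by number of high-risk disease flags
#'
#' Sorts patients by flag count (descending), breaking ties by total risk
#' z-score (descending) and then sample ID (ascending), and reports the
#' flagged diseases of each of the top `k`.
#'
#' @param risk A `risk_table` from [compute_risk_scores()].
#' @param k Number of patients to report (default 10).
#' @return Data frame with `rank`, `sample_id`, `n_flagged`, `total_z`,
#'   `flagged_diseases` (comma-separated).
#' @export
rank_high_risk_patients <- function(risk, k = 10L) {
  if (k < 1L) stop("rank_high_risk_patients: k must be >= 1", call. = FALSE)
  n <- nrow(risk$z)
  if (k > n) {
    warning("rank_high_risk_patients: k exceeds the cohort size; ",
            "returning all patients", call. = FALSE)
    k <- n
  }
  ids <- rownames(risk$z)
  n_flag <- rowSums(risk$high_risk)
  total_z <- rowSums(risk$z)
  ord <- order(-n_flag, -total_z, ids)
  top <- ord[seq_len(k)]
  flagged <- vapply(top, function(i) {
    paste(colnames(risk$high_risk)[risk$high_risk[i, ]], collapse = ",")
  }, character(1))
  data.frame(rank = seq_len(k),
             sample_id = ids[top],
             n_flagged = as.integer(n_flag[top]),
             total_z = total_z[top],
             flagged_diseases = flagged,
             stringsAsFactors = FALSE)
}
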