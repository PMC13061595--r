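#' Project CpG beta values onto protein EpiScores
#'
#' Computes each protein EpiScore as the weighted linear combination of a
#' sample's methylation beta values over that protein's CpG set:
#' `score(s, p) = sum_k w_k * beta_k(s)`. Probes absent from the methylation
#' matrix, or present but `NA` for a sample, are substituted by the
#' population reference mean beta — so a sample missing every probe of a
#' protein scores exactly the protein's reference baseline.
#'
#' @param meth Numeric matrix of beta values in `[0, 1]` (NA allowed),
#'   CpGs as rows and samples as columns by default.
#' @param weights Data frame with columns `protein_id`, `cpg_id`, `weight`.
#' @param ref_means Named numeric vector mapping CpG IDs to reference mean
#'   betas in `[0, 1]`.
#' @param orientation `"probes-rows"` (default) or `"samples-rows"`.
#' @param max_impute_fraction Proteins whose imputed-probe fraction exceeds
#'   this are flagged unreliable in the imputation report (default 0.2).
#' @return Numeric matrix samples x proteins with attribute
#'   `imputation_report`: a data frame (`protein_id`, `n_cpgs`,
#'   `n_imputed_probes`, `impute_fraction`, `unreliable`) where
#'   `n_imputed_probes` counts weighted probes entirely absent from `meth`
#'   and `impute_fraction` the mean per-sample fraction of imputed entries
#'   (absent probes plus per-sample NAs).
#' @export
project_episcores <- function(meth, weights, ref_means,
                              orientation = c("probes-rows", "samples-rows"),
                              max_impute_fraction = 0.2) {
  orientation <- match.arg(orientation)
  if (orientation == "samples-rows") meth <- t(meth)
  if (is.null(rownames(meth)))
    stop("project_episcores: methylation matrix must have CpG rownames",
         call. = FALSE)
  rng <- range(meth, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("project_episcores: beta values outside [0, 1] (range ",
         signif(rng[1], 4), "..", signif(rng[2], 4), ")", call. = FALSE)

  cpgs_needed <- unique(weights$cpg_id)
  absent <- setdiff(cpgs_needed, rownames(meth))
  unresolvable <- setdiff(absent, names(ref_means))
  if (length(unresolvable))
    stop("project_episcores: weighted CpG(s) absent from both the ",
         "methylation matrix and the reference means: ",
         paste(utils::head(unresolvable, 5L), collapse = ", "),
         if (length(unresolvable) > 5L) ", ...", call. = FALSE)

  n_samp <- ncol(meth)
  # full beta matrix over all weighted CpGs, imputing absent probes and NAs
  # from the reference means
  beta <- matrix(NA_real_, nrow = length(cpgs_needed), ncol = n_samp,
                 dimnames = list(cpgs_needed, colnames(meth)))
  present <- intersect(cpgs_needed, rownames(meth))
  beta[present, ] <- meth[present, , drop = FALSE]
  imputed <- is.na(beta)
  if (any(imputed)) {
    no_ref <- rownames(beta)[rowSums(imputed) > 0 &
                               !(rownames(beta) %in% names(ref_means))]
    if (length(no_ref))
      stop("project_episcores: missing betas at CpG(s) without a reference ",
           "mean: ", paste(utils::head(no_ref, 5L), collapse = ", "),
           call. = FALSE)
    idx <- which(imputed, arr.ind = TRUE)
    beta[idx] <- ref_means[rownames(beta)[idx[, 1]]]
  }

  proteins <- unique(weights$protein_id)
  W <- matrix(0, nrow = length(cpgs_needed), ncol = length(proteins),
              dimnames = list(cpgs_needed, proteins))
  W[cbind(match(weights$cpg_id, cpgs_needed),
          match(weights$protein_id, proteins))] <- weights$weight
  scores <- t(beta) %*% W

  per_protein <- vapply(proteins, function(p) {
    cp <- weights$cpg_id[weights$protein_id == p]
    c(n_cpgs = length(cp),
      n_absent = sum(cp %in% absent),
      frac = mean(imputed[cp, , drop = FALSE]))
  }, numeric(3))
  report <- data.frame(
    protein_id = proteins,
    n_cpgs = as.integer(per_protein["n_cpgs", ]),
    n_imputed_probes = as.integer(per_protein["n_absent", ]),
    impute_fraction = per_protein["frac", ],
    unreliable = per_protein["frac", ] > max_impute_fraction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(report$unreliable))
    warning("project_episcores: ", sum(report$unreliable), " protein(s) ",
            "exceed the maximum imputation fraction of ", max_impute_fraction,
            call. = FALSE)
  attr(scores, "imputation_report") <- report
  scores
}

#' Harmonize EpiScore names across naming conventions
#'
#' Maps raw EpiScore names (e.g., as emitted by a projection tool) onto the
#' standardized nomenclature used by published EpiScore-disease tables.
#' Distinct raw names resolving to the same standard name (platform
#' duplicates such as epitope variants) are kept as separate entries with a
#' disambiguating `.1`, `.2`, ... suffix and flagged.
#'
#' @param raw_names Character vector of names to resolve.
#' @param mapping Data frame with columns `raw_name`, `standard_name`
#'   (optionally `identifier`, `panel`, `note`).
#' @param strict If `TRUE` (default) an unmapped raw name is an error;
#'   otherwise it passes through unchanged with a warning.
#' @return Data frame with columns `raw_name`, `standard_name`, `resolved`
#'   (the possibly suffixed unique output name), `duplicate` (logical) and
#'   `mapped` (logical).
#' @export
harmonize_names <- function(raw_names, mapping, strict = TRUE) {
  if (anyDuplicated(mapping$raw_name))
    stop("harmonize_names: mapping contains duplicated raw names",
         call. = FALSE)
  idx <- match(raw_names, mapping$raw_name)
  std <- mapping$standard_name[idx]
  unmapped <- is.na(idx)
  if (any(unmapped)) {
    if (strict)
      stop("harmonize_names: unmapped raw name(s): ",
           paste(utils::head(raw_names[unmapped], 5L), collapse = ", "),
           call. = FALSE)
    warning("harmonize_names: ", sum(unmapped),
            " unmapped name(s) passed through unchanged", call. = FALSE)
    std[unmapped] <- raw_names[unmapped]
  }
  dup <- duplicated(std) | duplicated(std, fromLast = TRUE)
  resolved <- std
  for (s in unique(std[dup])) {
    at <- which(std == s)
    resolved[at] <- paste0(s, ".", seq_along(at))
  }
  data.frame(raw_name = raw_names, standard_name = std, resolved = resolved,
             duplicate = dup, mapped = !unmapped,
             stringsAsFactors = FALSE)
}

#' Z-score the columns of a matrix
#'
#' Transforms each column to `(x - mean) / sd` with the sample SD
#' (denominator n - 1). Used for fitness predictors before association
#' modeling, for EpiScores entering the direct risk term and for risk-score
#' normalization.
#'
#' @param x Numeric matrix (or data frame of numeric columns).
#' @return Matrix of the same shape with columns of mean 0 and SD 1, and
#'   attributes `center` and `scale`.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("standardize_columns: need at least 2 rows", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(x)[sds == 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | !is.finite(sds))
    stop("standardize_columns: constant or degenerate column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mus <- colMeans(x)
  out <- sweep(sweep(x, 2L, mus), 2L, sds, `/`)
  attr(out, "center") <- mus
  attr(out, "scale") <- sds
  out
}
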