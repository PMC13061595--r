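#' Ordinary least squares fit with classical standard errors
#'
#' QR-based least squares for a design matrix that already includes its
#' intercept column. Standard errors come from `sigma2 * (X'X)^-1` with
#' `sigma2 = RSS / df`, `df = n - ncol(X)`; p-values are two-sided from the
#' t distribution on `df`. `y` may be a matrix, in which case every response
#' column is fit against the same design in one decomposition (this is what
#' makes the 5 x 109-model association scan cheap).
#'
#' @param y Numeric response vector, or matrix with responses in columns.
#' @param X Numeric design matrix including an intercept column.
#' @return List with `coefficients`, `se`, `t`, `p` (each p_design x
#'   n_response matrices, or vectors for vector `y`), `df` and `r_squared`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  ymat <- as.matrix(y)
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(ymat) != n)
    stop("fit_ols: response and design have different row counts",
         call. = FALSE)
  if (n <= p)
    stop("fit_ols: need more observations than design columns", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < p) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    if (is.null(dep)) dep <- qrx$pivot[(qrx$rank + 1L):p]
    stop("fit_ols: rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qrx, ymat)
  fitted <- X %*% coef
  res <- ymat - fitted
  df <- n - p
  rss <- colSums(res^2)
  sigma2 <- rss / df
  # (X'X)^-1 from the R factor; columns are unpivoted for full-rank designs
  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)
  piv <- qrx$pivot
  xtx_inv[piv, piv] <- xtx_inv
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tstat <- coef / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  tss <- colSums(sweep(ymat, 2L, colMeans(ymat))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  dimnames(se) <- dimnames(coef)
  if (is.vector(y) || (is.matrix(y) && ncol(y) == 1L && is.null(colnames(y)))) {
    coef <- drop(coef); se <- drop(se); tstat <- drop(tstat)
    pval <- drop(pval); r2 <- unname(r2)
  }
  list(coefficients = coef, se = se, t = tstat, p = pval,
       df = df, r_squared = r2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, `q_i = min_{j >= i} p_j * m / j`,
#' restored to input order. Delegates to [stats::p.adjust()] after input
#' validation; tests hold it against a direct step-up evaluation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must be finite and in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted fitness-EpiScore association scan
#'
#' Fits one OLS model per (fitness trait, protein) pair:
#' `EpiScore ~ trait_z + sex + age`, where the trait is cohort z-scored and
#' age and sex (female = 0, male = 1) enter on their natural scales. Reports
#' the trait coefficient, its standard error, the two-sided p-value, and
#' BH q-values computed jointly across all trait x protein tests (or within
#' each trait with `fdr_family = "per-trait"`).
#'
#' @param episcores Numeric matrix samples x proteins (raw scale).
#' @param fitness Data frame with `sample_id` and the trait columns.
#' @param covariates Data frame with `sample_id`, `age`, `sex`.
#' @param alpha Significance threshold (default 0.05).
#' @param fdr_family `"global"` (default) or `"per-trait"` BH family.
#' @param traits Trait columns to scan; defaults to every non-ID column of
#'   `fitness`.
#' @return Data frame (class `association_table`) with one row per
#'   (trait, protein): `fitness_trait`, `protein_id`, `beta`, `se`,
#'   `p_value`, `q_value`, `significant_nominal`, `significant_fdr`.
#' @export
association_scan <- function(episcores, fitness, covariates, alpha = 0.05,
                             fdr_family = c("global", "per-trait"),
                             traits = setdiff(names(fitness), "sample_id")) {
  fdr_family <- match.arg(fdr_family)
  if (!(alpha > 0 && alpha < 1))
    stop("association_scan: alpha must be in (0, 1)", call. = FALSE)
  ids <- rownames(episcores)
  if (is.null(ids))
    stop("association_scan: episcores must carry sample_id rownames",
         call. = FALSE)
  if (!setequal(ids, fitness$sample_id) ||
      !setequal(ids, covariates$sample_id))
    stop("association_scan: sample IDs of episcores, fitness and covariates ",
         "do not match", call. = FALSE)
  fitness <- fitness[match(ids, fitness$sample_id), , drop = FALSE]
  covariates <- covariates[match(ids, covariates$sample_id), , drop = FALSE]

  fz <- standardize_columns(as.matrix(fitness[traits]))
  proteins <- colnames(episcores)
  out <- vector("list", length(traits))
  for (k in seq_along(traits)) {
    X <- cbind(intercept = 1, trait = fz[, k],
               sex = covariates$sex, age = covariates$age)
    fit <- fit_ols(episcores, X)
    out[[k]] <- data.frame(
      fitness_trait = traits[k],
      protein_id = proteins,
      beta = fit$coefficients["trait", ],
      se = fit$se["trait", ],
      p_value = fit$p["trait", ],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  tab <- do.call(rbind, out)
  tab$q_value <- if (fdr_family == "global") {
    bh_adjust(tab$p_value)
  } else {
    stats::ave(tab$p_value, tab$fitness_trait, FUN = bh_adjust)
  }
  tab$significant_nominal <- tab$p_value < alpha
  tab$significant_fdr <- tab$q_value < alpha
  class(tab) <- c("association_table", "data.frame")
  tab
}
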