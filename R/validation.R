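#' External CVD benchmark score
#'
#' Weighted sum of a fixed panel of protein EpiScores with externally
#' published weights: `score(s) = sum_i weight_i * episcore(s, i)`. Higher
#' values indicate higher epigenetic cardiovascular risk. By default the
#' same standardized EpiScore matrix used for the direct risk term is
#' expected, for internal consistency; pass the raw matrix to score on raw
#' EpiScores.
#'
#' @param episcores EpiScore matrix (samples x proteins).
#' @param cvd_weights Data frame with `protein_id`, `weight`.
#' @param strict If `TRUE` (default) a weighted protein absent from the
#'   matrix is an error; otherwise it is skipped with a warning.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_cvd_score <- function(episcores, cvd_weights, strict = TRUE) {
  missing_p <- setdiff(cvd_weights$protein_id, colnames(episcores))
  if (length(missing_p)) {
    msg <- paste0("CVD-weighted protein(s) absent from the EpiScore matrix: ",
                  paste(utils::head(missing_p, 5L), collapse = ", "))
    if (strict) stop("compute_cvd_score: ", msg, call. = FALSE)
    warning("compute_cvd_score: ", msg, "; skipped", call. = FALSE)
    cvd_weights <- cvd_weights[!cvd_weights$protein_id %in% missing_p, ,
                               drop = FALSE]
  }
  drop(episcores[, cvd_weights$protein_id, drop = FALSE] %*%
         cvd_weights$weight)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of mid-ranks (ties get average ranks); the
#' p-value comes from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom, two-sided. For `|rho| = 1` the p-value is 0.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("spearman_corr: unequal lengths", call. = FALSE)
  if (n < 3L) stop("spearman_corr: need at least 3 observations",
                   call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_corr: constant input", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Correlate disease risk scores with the CVD benchmark
#'
#' One correlation per disease between the per-sample CVD benchmark score
#' and that disease's risk score, with BH adjustment across diseases and
#' significance stars at FDR < 0.01 (`**`) and FDR < 0.001 (`***`).
#'
#' @param risk A `risk_table` from [compute_risk_scores()] (the z matrix is
#'   correlated; for Spearman this equals correlating the raw scores).
#' @param cvd_scores Named numeric vector of per-sample benchmark scores.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Data frame with `disease`, `coefficient`, `p_value`, `q_value`,
#'   `stars`.
#' @export
validate_against_benchmark <- function(risk, cvd_scores,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ids <- rownames(risk$z)
  if (is.null(names(cvd_scores)))
    stop("validate_against_benchmark: cvd_scores must be named by sample",
         call. = FALSE)
  if (!setequal(ids, names(cvd_scores)))
    stop("validate_against_benchmark: sample IDs do not match", call. = FALSE)
  cvd <- cvd_scores[ids]
  res <- lapply(colnames(risk$z), function(d) {
    if (method == "spearman") {
      s <- spearman_corr(cvd, risk$z[, d])
      c(s$rho, s$p_value)
    } else {
      ct <- stats::cor.test(cvd, risk$z[, d], method = "pearson")
      c(unname(ct$estimate), ct$p.value)
    }
  })
  out <- data.frame(disease = colnames(risk$z),
                    coefficient = vapply(res, `[`, numeric(1), 1L),
                    p_value = vapply(res, `[`, numeric(1), 2L),
                    stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out$stars <- ifelse(out$q_value < 0.001, "***",
                      ifelse(out$q_value < 0.01, "**", ""))
  out
}

#' Pairwise Pearson correlation matrix between two variable sets
#'
#' Convenience for the descriptive correlation outputs (fitness traits vs
#' disease risk scores; fitness, covariates and CVD score).
#'
#' @param x,y Numeric matrices or data frames with aligned rows; `y`
#'   defaults to `x`.
#' @param method Correlation method passed to [stats::cor()].
#' @return Correlation matrix (rows = columns of `x`, cols = columns of `y`).
#' @export
pairwise_correlations <- function(x, y = x, method = "pearson") {
  stats::cor(as.matrix(x), as.matrix(y), method = method)
}
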