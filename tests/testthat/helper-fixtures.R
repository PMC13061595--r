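# Small in-code fixtures shared across test files.

# A miniature study: 40 samples, 6 proteins x 4 CpGs, 3 diseases, 4 CVD
# weights. Effect matrix plants one strong BMI effect and one negative
# jump_max effect so linkage and indirect chains are non-empty.
tiny_spec <- function(seed = 11L, n_samples = 40L, noise_sd = 0.3) {
  em <- matrix(0, nrow = 5, ncol = 6,
               dimnames = list(fitness_traits(), sprintf("prot_%03d", 1:6)))
  em["bmi", 1] <- 0.5
  em["jump_max", 2] <- -0.4
  cohort_spec(n_samples = n_samples, n_proteins = 6L, cpgs_per_protein = 4L,
              n_diseases = 3L, n_cvd_proteins = 4L,
              proteins_per_disease = 3L,
              effect_matrix = em, noise_sd = noise_sd, seed = seed)
}

tiny_study <- function(seed = 11L, ...) {
  suppressWarnings(simulate_study(tiny_spec(seed = seed, ...)))
}

# Hand-built 1-protein / 3-CpG weight fixture used by projection and
# embedding examples.
toy_weights <- function() {
  data.frame(protein_id = "protA", cpg_id = c("cg1", "cg2", "cg3"),
             weight = c(0.2, -0.1, 0.3), stringsAsFactors = FALSE)
}

toy_ref <- function() c(cg1 = 0.5, cg2 = 0.5, cg3 = 0.5)

# Independent normal-equations OLS oracle: solve (X'X) b = X'y directly.
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tstat <- drop(b) / se
  list(coefficients = drop(b), se = se,
       p = 2 * pt(abs(tstat), df, lower.tail = FALSE), df = df)
}

# Direct step-up evaluation of Benjamini-Hochberg adjusted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force indirect risk: loop over every (trait, protein, disease) chain.
indirect_oracle <- function(fitness_std, sig, hazards) {
  diseases <- unique(hazards$disease)
  out <- matrix(0, nrow = nrow(fitness_std), ncol = length(diseases),
                dimnames = list(rownames(fitness_std), diseases))
  for (r in seq_len(nrow(sig))) {
    for (h in seq_len(nrow(hazards))) {
      if (sig$protein_id[r] == hazards$protein_id[h]) {
        out[, hazards$disease[h]] <- out[, hazards$disease[h]] +
          sig$beta[r] * hazards$log_hr[h] *
          fitness_std[, sig$fitness_trait[r]]
      }
    }
  }
  out
}

# Mid-rank-then-Pearson Spearman oracle using the explicit product-moment
# formula on average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
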