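std_mat <- function(m) {
  z <- standardize_columns(m)
  attributes(z)[c("center", "scale")] <- NULL
  z
}

test_that("direct risk term is the hand-computed hazard-weighted sum", {
  ep <- matrix(c(1, 2), 1, 2, dimnames = list("s1", c("pA", "pB")))
  hz <- data.frame(disease = "d", protein_id = c("pA", "pB"),
                   log_hr = c(0.3, -0.2))
  expect_equal(unname(compute_direct_risk(ep, hz)["s1", "d"]),
               0.3 * 1 - 0.2 * 2, tolerance = 1e-12)

  # identity: one protein with log HR 1 passes the score through
  hz1 <- data.frame(disease = "d", protein_id = "pA", log_hr = 1)
  expect_equal(unname(compute_direct_risk(ep, hz1)["s1", "d"]), 1)

  # null weights zero everything
  hz0 <- transform(hz, log_hr = 0)
  expect_equal(unname(compute_direct_risk(ep, hz0)["s1", "d"]), 0)
})

test_that("direct risk skips absent proteins with a warning and zeroes empty diseases", {
  ep <- matrix(1, 1, 1, dimnames = list("s1", "pA"))
  hz <- data.frame(disease = c("d1", "d2"), protein_id = c("pA", "pX"),
                   log_hr = c(0.5, 0.9))
  expect_warning(expect_warning(direct <- compute_direct_risk(ep, hz),
                                "skipped"),
                 "no scoring proteins")
  expect_equal(unname(direct["s1", "d2"]), 0)
  expect_equal(unname(direct["s1", "d1"]), 0.5)
})

test_that("indirect risk equals the single-chain product and sums additively", {
  fz <- matrix(2, 1, 1, dimnames = list("s1", "bmi"))
  sig <- data.frame(fitness_trait = "bmi", protein_id = "pA", beta = 0.5)
  hz <- data.frame(disease = "d", protein_id = "pA", log_hr = 0.2)
  expect_equal(unname(compute_indirect_risk(fz, sig, hz)["s1", "d"]),
               0.5 * 0.2 * 2, tolerance = 1e-12)

  # two chains through the same trait add up
  sig2 <- rbind(sig, data.frame(fitness_trait = "bmi", protein_id = "pB",
                                beta = -0.3))
  hz2 <- rbind(hz, data.frame(disease = "d", protein_id = "pB",
                              log_hr = 0.4))
  expect_equal(unname(compute_indirect_risk(fz, sig2, hz2)["s1", "d"]),
               0.5 * 0.2 * 2 + (-0.3) * 0.4 * 2, tolerance = 1e-12)

  # no significant associations -> zero with warning
  expect_warning(zero <- compute_indirect_risk(fz, sig[0, ], hz),
                 "no chain")
  expect_equal(unname(zero["s1", "d"]), 0)
})

test_that("indirect risk matches the brute-force chain enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    traits <- c("vo2max", "bmi", "cognition")
    fz <- matrix(rnorm(n * 3), n, dimnames = list(sprintf("s%02d", 1:n),
                                                  traits))
    sig <- data.frame(
      fitness_trait = sample(traits, 6, replace = TRUE),
      protein_id = sample(paste0("p", 1:4), 6, replace = TRUE),
      beta = rnorm(6))
    hz <- expand.grid(disease = c("d1", "d2"),
                      protein_id = paste0("p", 1:4),
                      stringsAsFactors = FALSE)
    hz$log_hr <- rnorm(nrow(hz), 0, 0.2)
    got <- compute_indirect_risk(fz, sig, hz)
    ora <- indirect_oracle(fz, sig, hz)
    expect_equal(got[, colnames(ora)], ora, tolerance = 1e-12)
  }
})

test_that("risk scores standardize per disease and flag strictly above threshold", {
  raw <- matrix(c(1, 2, 6, -1, 0, 1), 3, 2,
                dimnames = list(c("s1", "s2", "s3"), c("dA", "dB")))
  rt <- compute_risk_scores(raw)
  # hand z-scores for dA: mean 3, sd sqrt(7)
  expect_equal(unname(rt$z[, "dA"]), (c(1, 2, 6) - 3) / sqrt(7),
               tolerance = 1e-12)
  expect_lt(max(abs(colMeans(rt$z))), 1e-9)
  expect_lt(max(abs(apply(rt$z, 2, sd) - 1)), 1e-9)
  expect_identical(unname(rt$high_risk), unname(rt$z > 1.28))

  # additivity: direct + indirect enter as a plain sum before z-scoring
  direct <- raw; indirect <- matrix(0.5, 3, 2, dimnames = dimnames(raw))
  expect_equal(compute_risk_scores(direct, indirect)$raw, direct + indirect)

  # degenerate disease column
  expect_error(compute_risk_scores(matrix(1, 3, 1,
                                          dimnames = list(NULL, "d"))),
               "constant")
  expect_error(compute_risk_scores(raw, matrix(0, 2, 2)), "aligned")
})

test_that("flag fraction under normal scores approaches the 1.28 tail mass", {
  set.seed(77)
  n <- 50000
  raw <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("d1", "d2")))
  rt <- compute_risk_scores(raw)
  p <- pnorm(1.28, lower.tail = FALSE)  # 0.1003
  tol <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(rt$high_risk[, "d1"]) - p), tol)
})

test_that("fitness categorization matches hand thresholds and boundary rules", {
  ids <- sprintf("s%02d", 1:10)
  x <- c(10, 12, 14, 16, 18, 20, 22, 24, 26, 60)
  fitness <- data.frame(sample_id = ids, vo2max = x, cognition = x)
  cov <- data.frame(sample_id = ids, age = rep(55, 10), sex = rep(0, 10))
  cfg <- threshold_config(stratify_by_sex = FALSE)
  cats <- categorize_fitness(fitness, cov, cfg)
  m <- mean(x); s <- sd(x)
  expect_equal(cats$vo2max,
               ifelse(x < m - 1.28 * s, "low",
                      ifelse(x > m + 1.28 * s, "high", "normal")))
  # cognition: type-7 percentile boundaries, boundary value itself "normal"
  q <- quantile(x, c(0.1, 0.9), names = FALSE)
  expect_equal(cats$cognition,
               ifelse(x < q[1], "low", ifelse(x > q[2], "high", "normal")))
  # a value exactly at the upper percentile stays "normal"
  fitness2 <- fitness
  fitness2$cognition[1] <- q[2]
  cats2 <- categorize_fitness(fitness2, cov, cfg)
  expect_equal(cats2$cognition[1], "normal")
})

test_that("values at the stratum mean are normal; tiny strata fall back", {
  ids <- sprintf("s%02d", 1:21)
  age <- c(rep(55, 20), 85)  # one lone 80s participant
  fitness <- data.frame(sample_id = ids, bmi = c(rnorm(20, 26, 3), 26))
  cov <- data.frame(sample_id = ids, age = age, sex = rep(1, 21))
  expect_warning(cats <- categorize_fitness(fitness, cov,
                                            threshold_config()),
                 "cohort-wide")
  expect_equal(cats$bmi[21], "normal")  # at the cohort mean-ish center
  at <- cov$age < 60
  expect_equal(cats$bmi[1],
               ifelse(fitness$bmi[1] < mean(fitness$bmi[at]) -
                        1.28 * sd(fitness$bmi[at]), "low",
                      ifelse(fitness$bmi[1] > mean(fitness$bmi[at]) +
                               1.28 * sd(fitness$bmi[at]), "high",
                             "normal")))
})

test_that("normal-band fraction approaches Phi(1.28) - Phi(-1.28)", {
  set.seed(88)
  n <- 50000
  ids <- sprintf("s%05d", 1:n)
  fitness <- data.frame(sample_id = ids, vo2max = rnorm(n, 35, 7))
  cov <- data.frame(sample_id = ids, age = runif(n, 50, 59), sex = 0)
  cats <- categorize_fitness(fitness, cov, threshold_config())
  p_norm <- pnorm(1.28) - pnorm(-1.28)  # 0.7994
  expect_lt(abs(mean(cats$vo2max == "normal") - p_norm),
            3 * sqrt(p_norm * (1 - p_norm) / n) + 0.002)
})

test_that("patient ranking follows flags, then total z, then ID", {
  z <- matrix(c(2, 1.5, 0, -1, 0.5,
                2, 1.5, 2, -1, 0.4,
                2, -2, 1.29, -1, 0.3), 5, 3,
              dimnames = list(c("s5", "s2", "s3", "s4", "s1"),
                              c("d1", "d2", "d3")))
  rt <- list(raw = z, z = z, high_risk = z > 1.28, z_flag_threshold = 1.28)
  class(rt) <- "risk_table"
  ranked <- rank_high_risk_patients(rt, k = 5)
  # flags: s5 = 3; s2 = 2; s3 = 2 (1.29 > 1.28 counts); s4 = s1 = 0
  # ties: s3 total z = 3.29 beats s2 (1.0); s1 (1.2) beats s4 (-3)
  expect_equal(ranked$sample_id, c("s5", "s3", "s2", "s1", "s4"))
  expect_equal(ranked$n_flagged, c(3L, 2L, 2L, 0L, 0L))
  # all-zero flags rank purely by tie-breakers
  expect_true(all(ranked$n_flagged[4:5] == 0L))
  expect_warning(rank_high_risk_patients(rt, k = 10), "cohort size")
  expect_error(rank_high_risk_patients(rt, k = 0), "k must be")
})
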