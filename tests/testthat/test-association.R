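test_that("fit_ols matches the normal-equations oracle on a toy design", {
  X <- cbind(1, c(0, 1, 2, 3), c(1, 0, 1, 0))
  y <- c(1.1, 1.9, 3.2, 3.8)
  fit <- fit_ols(y, X)
  ora <- ols_oracle(y, X)
  expect_equal(unname(fit$coefficients), unname(ora$coefficients),
               tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(ora$se), tolerance = 1e-10)
  expect_equal(unname(fit$p), unname(ora$p), tolerance = 1e-10)
  expect_equal(fit$df, 1L)
})

test_that("fit_ols agrees with the oracle across random small designs", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(8:20, 1)
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    ora <- ols_oracle(y, X)
    expect_equal(unname(fit$coefficients), unname(ora$coefficients),
                 tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(ora$se), tolerance = 1e-8)
  }
})

test_that("fit_ols handles perfect fits, constant responses and collinearity", {
  x <- c(1, 2, 3, 4, 5)
  X <- cbind(intercept = 1, x = x)
  perfect <- fit_ols(x, X)
  expect_equal(unname(perfect$coefficients["x"]), 1, tolerance = 1e-12)
  expect_equal(unname(perfect$coefficients["intercept"]), 0,
               tolerance = 1e-12)

  const <- fit_ols(rep(4, 5), X)
  expect_equal(unname(const$coefficients), c(4, 0), tolerance = 1e-12)

  Xbad <- cbind(intercept = 1, a = x, b = 2 * x)
  expect_error(fit_ols(rnorm(5), Xbad), "collinear")
  expect_error(fit_ols(1:3, cbind(1, 1:3, rnorm(3))), "more observations")
})

test_that("matrix-response fit equals column-by-column fits", {
  set.seed(5)
  n <- 25
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("y", 1:4)))
  multi <- fit_ols(Y, X)
  for (j in 1:4) {
    single <- fit_ols(Y[, j], X)
    expect_equal(unname(multi$coefficients[, j]),
                 unname(single$coefficients), tolerance = 1e-12)
    expect_equal(unname(multi$p[, j]), unname(single$p), tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces hand-evaluated step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "finite")
})

test_that("bh_adjust matches the step-up oracle and is permutation-invariant", {
  set.seed(202)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

scan_fixture <- function(n = 400, beta = 0.4, seed = 9, n_prot = 3) {
  set.seed(seed)
  ids <- sprintf("s%04d", 1:n)
  cov <- data.frame(sample_id = ids, age = runif(n, 35, 85),
                    sex = rbinom(n, 1, 0.5))
  fit <- data.frame(sample_id = ids,
                    vo2max = rnorm(n, 35, 7), bmi = rnorm(n, 26, 4))
  ep <- matrix(rnorm(n * n_prot), n,
               dimnames = list(ids, paste0("p", seq_len(n_prot))))
  # plant bmi -> p1 plus age/sex confounding on every protein
  ep <- ep + 0.05 * cov$age + 0.3 * cov$sex
  ep[, "p1"] <- ep[, "p1"] + beta * scale(fit$bmi)[, 1]
  list(cov = cov, fit = fit, ep = ep)
}

test_that("association scan recovers a planted coefficient despite confounding", {
  fx <- scan_fixture(n = 2000, beta = 0.4)
  tab <- association_scan(fx$ep, fx$fit, fx$cov)
  expect_equal(nrow(tab), 2 * 3)  # traits x proteins
  hit <- tab[tab$fitness_trait == "bmi" & tab$protein_id == "p1", ]
  expect_lt(abs(hit$beta - 0.4), 3 * hit$se)
  expect_true(hit$significant_nominal)
})

test_that("association scan equals per-pair fit_ols fits", {
  fx <- scan_fixture(n = 120)
  tab <- association_scan(fx$ep, fx$fit, fx$cov)
  for (r in sample(nrow(tab), 4)) {
    row <- tab[r, ]
    tz <- scale(fx$fit[[row$fitness_trait]])[, 1]
    X <- cbind(1, tz, fx$cov$sex, fx$cov$age)
    ref <- fit_ols(fx$ep[, row$protein_id], X)
    expect_equal(row$beta, unname(ref$coefficients[2]), tolerance = 1e-10)
    expect_equal(row$p_value, unname(ref$p[2]), tolerance = 1e-10)
  }
})

test_that("scan coefficients are invariant to shifting age by a constant", {
  fx <- scan_fixture(n = 150)
  tab1 <- association_scan(fx$ep, fx$fit, fx$cov)
  fx$cov$age <- fx$cov$age + 100
  tab2 <- association_scan(fx$ep, fx$fit, fx$cov)
  expect_equal(tab1$beta, tab2$beta, tolerance = 1e-9)
  expect_equal(tab1$p_value, tab2$p_value, tolerance = 1e-9)
})

test_that("scan validates alignment, alpha and degenerate traits", {
  fx <- scan_fixture(n = 50)
  bad <- fx$fit
  bad$sample_id[1] <- "nope"
  expect_error(association_scan(fx$ep, bad, fx$cov), "sample ID")
  expect_error(association_scan(fx$ep, fx$fit, fx$cov, alpha = 0), "alpha")
  fx$fit$bmi <- 5
  expect_error(association_scan(fx$ep, fx$fit, fx$cov), "constant")
})

test_that("per-trait FDR family adjusts within each trait", {
  fx <- scan_fixture(n = 120)
  tab <- association_scan(fx$ep, fx$fit, fx$cov, fdr_family = "per-trait")
  for (tr in unique(tab$fitness_trait)) {
    sub <- tab[tab$fitness_trait == tr, ]
    expect_equal(sub$q_value, bh_oracle(sub$p_value), tolerance = 1e-12)
  }
})

test_that("default study scan yields 545 rows and finds the planted pattern", {
  st <- suppressWarnings(simulate_study(cohort_spec(seed = 2L)))
  sc <- project_episcores(st$methylation, st$weights, st$ref_means)
  tab <- association_scan(sc, st$fitness, st$covariates)
  expect_equal(nrow(tab), 545L)
  planted <- st$spec$effect_matrix != 0
  hit_rate <- mean(tab$significant_nominal[planted[cbind(
    match(tab$fitness_trait, rownames(planted)),
    match(tab$protein_id, colnames(planted)))]])
  expect_gt(hit_rate, 0.9)  # beta = 0.35 at n = 290, noise 0.5: high power
})
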