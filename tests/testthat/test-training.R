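p <- reg_probes()
age_probes <- unname(p[c("alpha", "beta", "gamma")])

# cohort whose ages follow the printed swab model exactly (no noise)
swab_exact_cohort <- function(n = 12, seed = 1) {
  set.seed(seed)
  # beta ranges chosen so the printed swab formula yields positive ages
  b <- cbind(runif(n, 0, 0.5), runif(n, 0, 0.3), runif(n, 0.1, 0.9))
  dimnames(b) <- list(sprintf("S%02d", seq_len(n)), age_probes)
  bm <- beta_matrix(b)
  bm$samples$age_years <- as.numeric(predict(published_models()$swab3, bm))
  bm
}

test_that("OLS age-model fitting interpolates noiseless data and matches the normal equations", {
  bm <- swab_exact_cohort()
  fit <- fit_age_model(bm, age_probes)
  expect_equal(unname(coef(fit$model)), c(32.69, -8.42, -47.38, 183.25),
               tolerance = 1e-6)
  expect_equal(fit$residual_mad, 0, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_identical(fit$n_samples, 12L)

  # constant age: intercept = that age, slopes 0
  bm2 <- random_beta_matrix(8, age_probes, seed = 2)
  bm2$samples$age_years <- 40
  fit2 <- fit_age_model(bm2, age_probes)
  expect_equal(unname(coef(fit2$model)), c(40, 0, 0, 0), tolerance = 1e-9)
  expect_true(is.na(fit2$r2))

  # random designs agree with an independent normal-equations oracle
  for (i in 1:20) {
    bm3 <- random_beta_matrix(20, age_probes, seed = 100 + i, with_ages = TRUE)
    fit3 <- fit_age_model(bm3, age_probes)
    oracle <- ne_oracle(cbind(1, bm3$betas), bm3$samples$age_years)
    expect_equal(unname(coef(fit3$model)), unname(oracle), tolerance = 1e-8)
  }
})

test_that("age-model fitting rejects degenerate designs and short data", {
  bm <- random_beta_matrix(10, age_probes, seed = 3, with_ages = TRUE)
  bm$betas[, 2] <- 0.5  # constant column
  expect_error(fit_age_model(bm, age_probes), "rank deficient.*cg25809905")
  bm2 <- random_beta_matrix(4, age_probes, seed = 4, with_ages = TRUE)
  expect_error(fit_age_model(bm2, age_probes), "at least 5")
  # samples with missing age or beta are excluded and listed
  bm3 <- random_beta_matrix(10, age_probes, seed = 5, with_ages = TRUE)
  bm3$samples$age_years[1] <- NA
  bm3$betas[2, 1] <- NA
  fit <- fit_age_model(bm3, age_probes)
  expect_identical(fit$n_samples, 8L)
  expect_setequal(fit$excluded$sample_id, c("S01", "S02"))
})

test_that("one-CpG fitting recovers the printed line, matches the closed form and detects flat fits", {
  g <- p[["gamma"]]
  n <- 55
  set.seed(10)
  ages <- runif(n, 1, 85)
  exact <- matrix(0.0648 + 0.0046 * ages, ncol = 1, dimnames = list(NULL, g))
  rownames(exact) <- sprintf("S%02d", 1:n)
  bm <- beta_matrix(exact, data.frame(sample_id = rownames(exact),
                                      age_years = ages))
  fit <- fit_one_cpg_model(bm, g)
  expect_equal(unname(coef(fit$model)), c(0.0648, 0.0046), tolerance = 1e-9)

  # noisy data: slope and intercept equal the simple-regression closed form
  noisy <- pmin(pmax(exact + rnorm(n, 0, 0.02), 0), 1)
  bm2 <- beta_matrix(noisy, bm$samples)
  fit2 <- fit_one_cpg_model(bm2, g)
  slope <- stats::cov(ages, noisy[, 1]) / stats::var(ages)
  beta0 <- mean(noisy[, 1]) - slope * mean(ages)
  expect_equal(unname(coef(fit2$model)), c(beta0, slope), tolerance = 1e-10)

  # age-independent beta: the line cannot be inverted
  flat <- matrix(0.3, n, 1, dimnames = list(rownames(exact), g))
  expect_error(fit_one_cpg_model(beta_matrix(flat, bm$samples), g),
               "not invertible")
  expect_error(fit_one_cpg_model(bm[1:2, ], g), "at least 3")
})

test_that("signature calibration reproduces exact linear counts and reports per-CpG fits", {
  d <- p[["delta"]]; e <- p[["epsilon"]]
  n <- 11
  set.seed(20)
  counted <- seq(37, 88, length.out = n)
  betas <- cbind((counted - 1.92) / 99.8, (counted - 88.54) / -98.12)
  dimnames(betas) <- list(sprintf("S%02d", 1:n), c(d, e))
  smp <- data.frame(sample_id = rownames(betas), age_years = NA_real_,
                    pct_epithelial_counted = counted)
  fit <- calibrate_cell_signature(beta_matrix(betas, smp), d, e)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$residual_mad, 0, tolerance = 1e-8)
  expect_equal(unname(fit$model$cal_delta), c(99.8, 1.92), tolerance = 1e-6)
  pred <- predict(fit$model, beta_matrix(betas, smp))
  expect_equal(as.numeric(pred), counted, tolerance = 1e-8)

  # noisy calibration: each line equals its closed-form simple regression,
  # and the combined R^2 is at least the weaker per-CpG R^2
  nb <- pmin(pmax(betas + rnorm(2 * n, 0, 0.02), 0), 1)
  fit2 <- calibrate_cell_signature(beta_matrix(nb, smp), d, e)
  sl <- stats::cov(nb[, 1], counted) / stats::var(nb[, 1])
  expect_equal(unname(fit2$model$cal_delta),
               c(sl, mean(counted) - sl * mean(nb[, 1])), tolerance = 1e-10)
  expect_gte(fit2$r2, min(fit2$r2_delta, fit2$r2_epsilon) - 1e-12)

  # too few samples / degenerate counts
  expect_error(calibrate_cell_signature(beta_matrix(nb, smp)[1:2, ], d, e),
               "at least 3")
  smp$pct_epithelial_counted <- 50
  expect_error(calibrate_cell_signature(beta_matrix(betas, smp), d, e),
               "zero variance")
})

test_that("the two-stage epithelial estimation recovers generating coefficients at zero noise", {
  m <- published_models()
  specs <- paperlike_cell_specs()
  co <- generate_cohort(specs$leuko, specs$epi,
                        cohort_spec(seed = 77, noise_sd = 0))
  fit <- fit_epithelial_age_model(co, m$blood3, m$signature)
  expect_equal(coef(fit$model$epithelial), coef(m$mix5$epithelial),
               tolerance = 1e-6)
  expect_equal(fit$residual_mad, 0, tolerance = 1e-8)
  # and agrees with a weighted normal-equations oracle on noisy data
  co2 <- generate_cohort(specs$leuko, specs$epi, cohort_spec(seed = 78))
  fit2 <- fit_epithelial_age_model(co2, m$blood3, m$signature)
  w <- as.numeric(predict(m$signature, co2)) / 100
  r <- co2$samples$age_years - (1 - w) * as.numeric(predict(m$blood3, co2))
  D <- w * cbind(1, co2$betas[, age_probes])
  expect_equal(unname(coef(fit2$model$epithelial)), unname(ne_oracle(D, r)),
               tolerance = 1e-8)
})

test_that("epithelial estimation reduces to plain OLS at 100% epithelium and fails at 0%", {
  set.seed(30)
  n <- 20
  X <- matrix(runif(n * 3), n, dimnames = list(sprintf("S%02d", 1:n),
                                               age_probes))
  full <- cbind(X, matrix(rep(c(1, 0), each = n), n,
                          dimnames = list(NULL, c(p[["delta"]], p[["epsilon"]]))))
  smp <- data.frame(sample_id = rownames(X), age_years = runif(n, 1, 85))
  bm <- beta_matrix(full, smp)
  # a signature that reads exactly 100% at delta=1, epsilon=0
  sig100 <- cell_signature(p[["delta"]], p[["epsilon"]],
                           cal_delta = c(100, 0), cal_epsilon = c(-100, 100))
  blood <- published_models()$blood3
  fit <- fit_epithelial_age_model(bm, blood, sig100, probes = age_probes)
  plain <- fit_age_model(bm, age_probes)
  expect_equal(coef(fit$model$epithelial), coef(plain$model),
               tolerance = 1e-10, ignore_attr = TRUE)

  # all fractions zero: published signature clamps delta=0/epsilon=1 to 0%
  full0 <- cbind(X, matrix(rep(c(0, 1), each = n), n,
                           dimnames = list(NULL, c(p[["delta"]], p[["epsilon"]]))))
  bm0 <- beta_matrix(full0, smp)
  expect_error(fit_epithelial_age_model(bm0, blood,
                                        published_models()$signature),
               "unidentifiable")
})

test_that("every fitted mixture beats the unadjusted blood model on heterogeneous cohorts", {
  m <- published_models()
  specs <- paperlike_cell_specs()
  for (s in 1:5) {
    co <- generate_cohort(specs$leuko, specs$epi, cohort_spec(seed = 900 + s))
    fit <- fit_epithelial_age_model(co, m$blood3, m$signature)
    blood_mad <- mean(abs_errors(as.numeric(predict(m$blood3, co)), co))
    expect_lt(fit$residual_mad, blood_mad)
  }
})
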