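specs <- paperlike_cell_specs()

test_that("cohort generation is deterministic in the seed and bounded in [0,1]", {
  cs <- cohort_spec(seed = 123)
  c1 <- generate_cohort(specs$leuko, specs$epi, cs)
  c2 <- generate_cohort(specs$leuko, specs$epi, cs)
  expect_identical(c1$betas, c2$betas)
  expect_identical(c1$samples, c2$samples)
  c3 <- generate_cohort(specs$leuko, specs$epi, cohort_spec(seed = 124))
  expect_false(identical(c1$betas, c3$betas))
  expect_true(all(c1$betas >= 0 & c1$betas <= 1))
  # and generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_cohort(specs$leuko, specs$epi, cs))
  expect_identical(runif(1), before)
})

test_that("at zero noise the emitted betas are exact mixtures of the cell-type curves", {
  cs <- cohort_spec(n_samples = 30, noise_sd = 0, seed = 5)
  co <- generate_cohort(specs$leuko, specs$epi, cs,
                        marker_mixing = "proportional")
  ages <- co$samples$age_years
  w <- co$samples$true_fraction / 100
  for (i in seq_len(nrow(specs$leuko$params))) {
    pl <- specs$leuko$params[i, ]
    pe <- specs$epi$params[match(pl$probe_id, specs$epi$params$probe_id), ]
    expected <- (1 - w) * (pl$intercept + pl$slope * ages) +
      w * (pe$intercept + pe$slope * ages)
    expect_equal(unname(co$betas[, pl$probe_id]), expected, tolerance = 1e-12)
  }

  # pure epithelium reproduces the epithelial curves exactly
  pure <- generate_cohort(specs$leuko, specs$epi,
                          cohort_spec(n_samples = 10, noise_sd = 0,
                                      fraction_range = c(100, 100), seed = 6),
                          marker_mixing = "proportional")
  pe <- specs$epi$params
  for (i in seq_len(nrow(pe))) {
    expect_equal(unname(pure$betas[, pe$probe_id[i]]),
                 pe$intercept[i] + pe$slope[i] * pure$samples$age_years,
                 tolerance = 1e-12)
  }
})

test_that("signature-consistent cohorts make the frozen mixture model exact at zero noise", {
  m <- published_models()
  co <- generate_cohort(specs$leuko, specs$epi,
                        cohort_spec(seed = 9, noise_sd = 0))
  pr <- predict(m$mix5, co)
  expect_equal(pr$age, co$samples$age_years, tolerance = 1e-9)
  expect_equal(pr$fraction, co$samples$true_fraction, tolerance = 1e-9)
  # marker betas are linear interpolations between the pure baselines
  sig <- m$signature
  base <- function(spec, pr_) spec$params$intercept[spec$params$probe_id == pr_]
  s0 <- as.numeric(predict(sig, stats::setNames(
    c(base(specs$leuko, sig$probe_delta), base(specs$leuko, sig$probe_epsilon)),
    c(sig$probe_delta, sig$probe_epsilon))))
  s1 <- as.numeric(predict(sig, stats::setNames(
    c(base(specs$epi, sig$probe_delta), base(specs$epi, sig$probe_epsilon)),
    c(sig$probe_delta, sig$probe_epsilon))))
  u <- (co$samples$true_fraction - s0) / (s1 - s0)
  expect_equal(unname(co$betas[, sig$probe_delta]),
               (1 - u) * base(specs$leuko, sig$probe_delta) +
                 u * base(specs$epi, sig$probe_delta), tolerance = 1e-12)
})

test_that("sampled ages and fractions cover the configured study conditions", {
  cs <- cohort_spec(n_samples = 55, seed = 1)
  co <- generate_cohort(specs$leuko, specs$epi, cs)
  frac <- co$samples$true_fraction
  expect_true(all(frac >= 24 & frac <= 91))
  expect_true(all(co$samples$age_years >= 1 & co$samples$age_years <= 85))
  # sample mean of the fractions within 3 standard errors of the uniform mean
  se <- (91 - 24) / sqrt(12) / sqrt(55)
  expect_lt(abs(mean(frac) - (24 + 91) / 2), 3 * se)
})

test_that("clipping is counted and impossible specs are rejected at construction", {
  noisy <- generate_cohort(specs$leuko, specs$epi,
                           cohort_spec(seed = 2, noise_sd = 0.5))
  expect_gt(attr(noisy, "n_clipped"), 0)
  expect_true(all(noisy$betas >= 0 & noisy$betas <= 1))
  quiet <- generate_cohort(specs$leuko, specs$epi,
                           cohort_spec(seed = 2, noise_sd = 0))
  expect_identical(attr(quiet, "n_clipped"), 0L)

  runaway <- cell_type_spec(
    "bad", age_cpg_params = data.frame(probe_id = "P", intercept = 0.5,
                                       slope = 0.02))
  other <- cell_type_spec(
    "ok", age_cpg_params = data.frame(probe_id = "P", intercept = 0.5,
                                      slope = 0))
  expect_error(generate_cohort(runaway, other, cohort_spec(seed = 1)),
               "outside \\[0,1\\]")
  expect_error(cohort_spec(seed = 1, fraction_range = c(-5, 50)), "fraction")
  expect_error(cohort_spec(n_samples = 10), "seed")
})

test_that("beta-distributed noise stays in bounds and respects the seed", {
  cs <- cohort_spec(n_samples = 40, seed = 31, noise_sd = 0.05)
  b1 <- generate_cohort(specs$leuko, specs$epi, cs, noise_model = "beta")
  b2 <- generate_cohort(specs$leuko, specs$epi, cs, noise_model = "beta")
  expect_identical(b1$betas, b2$betas)
  expect_true(all(b1$betas >= 0 & b1$betas <= 1))
  # distinct from the gaussian draw under the same seed
  g <- generate_cohort(specs$leuko, specs$epi, cs)
  expect_false(identical(b1$betas, g$betas))
})

test_that("calibration sets pair betas with counted fractions usable downstream", {
  p <- reg_probes()
  cal <- generate_calibration_set(specs$leuko, specs$epi, n = 11,
                                  noise_sd = 0, seed = 21)
  expect_identical(nrow(cal$cytology), 11L)
  expect_true(all(cal$cytology$pct_epithelial >= 37 &
                    cal$cytology$pct_epithelial <= 88))
  fit <- calibrate_cell_signature(cal$data, p[["delta"]], p[["epsilon"]])
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  pred <- predict(fit$model, cal$data)
  expect_equal(as.numeric(pred), cal$cytology$pct_epithelial, tolerance = 1e-6)

  # a two-sample calibration set generates, but calibration fails as specified
  tiny <- generate_calibration_set(specs$leuko, specs$epi, n = 2, seed = 22)
  expect_error(calibrate_cell_signature(tiny$data, p[["delta"]], p[["epsilon"]]),
               "at least 3")
})

test_that("decoy probes are age-independent and shared between the cell types", {
  sp <- paperlike_cell_specs(n_decoys = 10, decoy_seed = 3)
  expect_identical(nrow(sp$leuko$params), 15L)
  dec_l <- sp$leuko$params[grepl("^decoy", sp$leuko$params$probe_id), ]
  dec_e <- sp$epi$params[grepl("^decoy", sp$epi$params$probe_id), ]
  expect_identical(dec_l$intercept, dec_e$intercept)
  expect_true(all(dec_l$slope == 0))
  expect_true(all(dec_l$bio_sd > 0))
  # same decoy seed, same panel
  sp2 <- paperlike_cell_specs(n_decoys = 10, decoy_seed = 3)
  expect_identical(sp2$leuko$params, sp$leuko$params)
})
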