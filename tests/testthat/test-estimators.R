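test_that("complete-case fit equals the observed-case mean difference", {
  d <- trial_data(arm = rep(0:1, each = 3), y = c(1, 3, NA, 4, 6, NA))
  fit <- cca_fit(d)
  expect_equal(fit$estimate, 3)
  expect_equal(fit$retained_per_arm, c(2L, 2L))
  expect_error(cca_fit(trial_data(arm = rep(0:1, each = 3),
                                  y = c(1, NA, NA, 4, 6, 5))),
               "2 complete cases")
})

test_that("collinear covariates are rejected", {
  set.seed(51)
  d <- trial_data(arm = rep(0:1, each = 20), y = rnorm(40),
                  covariates = data.frame(a = rnorm(40)))
  d$b <- 2 * d$a
  expect_error(cca_fit(d, c("a", "b")), "collinear")
})

test_that("TM fit without covariates equals the difference of trimmed means", {
  d <- trial_data(arm = rep(0:1, each = 4), y = c(1, 2, 3, 4, 2, 3, 4, 5))
  expect_equal(tm_fit(d, trim_spec(0.5))$estimate, 1)
  set.seed(52)
  d2 <- generate_trial(trial_design(60, effect = 0.4), seed = 52)
  d2 <- apply_dropout(d2, mech_restricted(0, 0.1, 0.3), seed = 53)
  fit <- tm_fit(d2, trim_spec(0.3))
  tr <- tm_trim(d2, trim_spec(0.3))
  expect_equal(fit$estimate,
               mean(tr$y[tr$arm == 1]) - mean(tr$y[tr$arm == 0]),
               tolerance = 1e-10)
})

test_that("estimators are shift- and scale-equivariant", {
  set.seed(54)
  d <- generate_trial(trial_design(100, effect = 0.5), seed = 54)
  d <- apply_dropout(d, mech_restricted(0, 0.15, 0.4), seed = 55)
  spec <- trim_spec(0.5)
  base <- c(cca = cca_fit(d)$estimate, tm = tm_fit(d, spec)$estimate,
            at0 = adjusted_tm_fit(d, spec, 0)$estimate)
  shifted <- d; shifted$y <- shifted$y + 7
  scaled <- d; scaled$y <- scaled$y * 3
  got_shift <- c(cca = cca_fit(shifted)$estimate,
                 tm = tm_fit(shifted, spec)$estimate,
                 at0 = adjusted_tm_fit(shifted, spec, 0)$estimate)
  got_scale <- c(cca = cca_fit(scaled)$estimate,
                 tm = tm_fit(scaled, spec)$estimate,
                 at0 = adjusted_tm_fit(scaled, spec, 0)$estimate)
  expect_equal(got_shift, base, tolerance = 1e-10)
  expect_equal(got_scale, 3 * base, tolerance = 1e-10)
})

test_that("adjusted TM reduces to TM for equal-SD arms without dropout", {
  # quantile-exact normal samples: no sampling noise in the comparison
  n <- 20000
  z <- qnorm((seq_len(n) - 0.5) / n)
  d <- trial_data(arm = rep(0:1, each = n), y = c(z, z + 0.5))
  spec <- trim_spec(0.5)
  tm <- tm_fit(d, spec)$estimate
  expect_equal(adjusted_tm_fit(d, spec, 0)$estimate, tm, tolerance = 0.01)
  expect_equal(adjusted_tm_fit(d, spec, 1)$estimate, tm, tolerance = 0.01)
  expect_equal(tm, 0.5, tolerance = 0.01)
})

test_that("adjusted TM requires 50% fixed trimming", {
  d <- toy_trial()
  expect_error(adjusted_tm_fit(d, trim_spec(0.4)), "50%")
  expect_error(adjusted_tm_fit(d, trim_spec(mode = "adaptive")), "50%")
})

test_that("adjusted TM recovers the effect under unequal SDs when dropout is confined", {
  # the location-shift assumption is violated (sigma0 = 1.5) but dropout stays
  # inside the trimmed fraction, so rescaling restores unbiasedness
  set.seed(56)
  est <- replicate(150, {
    d <- generate_trial(trial_design(250, effect = 0.5, arm_sigmas = c(1.5, 1)))
    d <- apply_dropout(d, mech_restricted(0, 0.2, 0.2))
    adjusted_tm_fit(d, trim_spec(0.5), 0)$estimate
  })
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(length(est)))
  # while the unadjusted TM is biased towards the null by (sigma1-sigma0)*sqrt(2/pi)
  set.seed(56)
  tm <- replicate(150, {
    d <- generate_trial(trial_design(250, effect = 0.5, arm_sigmas = c(1.5, 1)))
    d <- apply_dropout(d, mech_restricted(0, 0.2, 0.2))
    tm_fit(d, trim_spec(0.5))$estimate
  })
  expect_lt(abs(mean(tm) - (0.5 - 0.5 * sqrt(2 / pi))),
            3 * sd(tm) / sqrt(length(tm)))
})

test_that("permutation interval is deterministic given a seed and brackets the estimate", {
  set.seed(57)
  d <- generate_trial(trial_design(60, effect = 0.8), seed = 57)
  d <- apply_dropout(d, mech_restricted(0, 0.1, 0.1), seed = 58)
  a <- permutation_ci(d, trim_spec(0.5), n_perm = 200, seed = 99)
  b <- permutation_ci(d, trim_spec(0.5), n_perm = 200, seed = 99)
  expect_identical(a, b)
  expect_lte(a$ci[1], a$estimate)
  expect_gte(a$ci[2], a$estimate)
  expect_gt(a$se, 0)
})

test_that("permutation interval covers a null effect at roughly the nominal rate", {
  set.seed(59)
  covered <- replicate(30, {
    d <- generate_trial(trial_design(40, effect = 0))
    ci <- permutation_ci(d, trim_spec(0.25), n_perm = 150)$ci
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gte(mean(covered), 0.8)
})

test_that("covariate imputation is a no-op when complete, reproducible, and pooled fits are unbiased", {
  set.seed(60)
  d <- generate_trial(trial_design(100, effect = 1, arm_sigmas = c(2, 2),
                                   covariate_effect = 1), seed = 60)
  expect_identical(impute_covariate(d, "u"), d)

  d2 <- apply_covariate_missingness(d, mech_logit(-1, 0, c(0, 0.5)), seed = 61)
  trimmed <- tm_trim(d2, trim_spec(0.5))
  i1 <- impute_covariate(trimmed, "u", n_imputations = 3, seed = 7)
  i2 <- impute_covariate(trimmed, "u", n_imputations = 3, seed = 7)
  expect_identical(i1, i2)
  expect_length(i1, 3)
  expect_false(anyNA(i1[[1]]$u))
  fit <- tm_fit_pooled(i1, trim_spec(0.5), "u")
  expect_true(is.finite(fit$estimate) && is.finite(fit$se))
  expect_equal(fit$n_imputations, 3)
})

test_that("missing-covariate rows stop the TM fit unless imputation or dropping is chosen", {
  set.seed(62)
  d <- generate_trial(trial_design(50, effect = 1, arm_sigmas = c(2, 2),
                                   covariate_effect = 1), seed = 62)
  d <- apply_covariate_missingness(d, mech_logit(-1), seed = 63)
  expect_error(tm_fit(d, trim_spec(0.5), "u"), "impute_covariate")
  fit <- tm_fit(d, trim_spec(0.5), "u", covariate_missing = "drop")
  expect_true(is.finite(fit$estimate))
})
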