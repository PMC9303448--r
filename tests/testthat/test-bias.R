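test_that("location-shift bias matches the closed form and flips with direction", {
  expect_equal(round(location_shift_bias(1, 1.5, 0.5), 2), -0.40)
  expect_equal(location_shift_bias(1, 1.5, 0.5), -0.5 * sqrt(2 / pi),
               tolerance = 1e-12)
  expect_equal(location_shift_bias(2, 2, 0.3), 0)
  expect_equal(location_shift_bias(1, 1.5, 0.3, "higher"),
               -location_shift_bias(1, 1.5, 0.3, "lower"))
  expect_error(location_shift_bias(1, 1.5, 1), "\\(0, 1\\)")
})

test_that("general-p location-shift bias matches a large-sample trimming oracle", {
  # trimmed-mean difference of two dropout-free normal arms, p = 0.3
  set.seed(71)
  n <- 2e6
  y0 <- rnorm(n, sd = 1.5)
  y1 <- rnorm(n, sd = 1)
  t0 <- mean(y0[y0 > quantile(y0, 0.3)])
  t1 <- mean(y1[y1 > quantile(y1, 0.3)])
  expect_equal(location_shift_bias(1, 1.5, 0.3), t1 - t0, tolerance = 0.005)
})

test_that("strong-MNAR shift quantile behaves across regimes", {
  expect_equal(strong_mnar_shift(0.5, 1, 0.2), 0.375)
  expect_equal(strong_mnar_shift(0.5, 0.8, 0), 0.5)
  expect_equal(strong_mnar_shift(0.5, 0.4, 0.2), 0.5) # spread inside trim
  expect_error(strong_mnar_shift(0.5, 1, 0.6), "infeasible")
  # b decreases as dropout grows
  b <- vapply(c(0, 0.1, 0.2, 0.3, 0.4), strong_mnar_shift, numeric(1),
              p = 0.5, c = 1)
  expect_true(all(diff(b) < 0))
  # empirical-quantile oracle: delete 20% uniformly, find where the top half
  # of the padded sample starts
  set.seed(72)
  n <- 1e6
  z <- sort(rnorm(n))
  obs <- sort(z[-sample.int(n, 0.2 * n)])
  start <- length(obs) - ceiling(0.5 * n) + 1L
  expect_equal(pnorm(obs[start]), 0.375, tolerance = 0.005)
})

test_that("strong-MNAR bias reproduces the printed closed-form values", {
  expect_equal(round(strong_mnar_bias(1, 0.5, 1, 0.2), 2), 0.19)
  expect_equal(round(strong_mnar_bias(1, 0.5, 0.75, 0.2), 2), 0.06)
  expect_equal(round(strong_mnar_bias(1.5, 0.5, 1, 0.2), 2), 0.29)
  expect_equal(strong_mnar_bias(1, 0.5, 0.4, 0.2), 0)
  expect_equal(strong_mnar_bias(1.5, 0.5, 1, 0.2),
               1.5 * strong_mnar_bias(1, 0.5, 1, 0.2), tolerance = 1e-12)
})

test_that("strong-MNAR bias is monotone in spread and dropout and maximal at MCAR", {
  cs <- seq(0.55, 1, by = 0.05)
  vals_c <- vapply(cs, function(cc) strong_mnar_bias(1, 0.5, cc, 0.2), numeric(1))
  expect_true(all(diff(vals_c) > 0))
  pds <- seq(0, 0.5, by = 0.05)
  vals_pd <- vapply(pds, function(pd) strong_mnar_bias(1, 0.5, 0.9, pd), numeric(1))
  expect_true(all(diff(vals_pd) >= 0))
})

test_that("complete-case bias matches Monte-Carlo deletion oracles", {
  expect_equal(cca_bias(1, 0.2, 0.2), -truncated_mean(0, 1, 0.2, 1),
               tolerance = 1e-12)
  expect_equal(cca_bias(1, 1, 0.2), 0)
  expect_equal(cca_bias(3, 0.5, 0), 0)
  set.seed(73)
  for (sc in list(c(0.2, 0.2), c(0.75, 0.2), c(0.5, 0.3))) {
    oracle <- mc_cca_bias(sc[1], sc[2])
    expect_lt(abs(cca_bias(1, sc[1], sc[2]) - oracle[["bias"]]),
              3 * oracle[["se"]])
  }
  expect_error(cca_bias(1, 0.2, 0.5), "exceed")
})

test_that("the Copas-Jackson bound dominates and is attained at full directionality", {
  expect_equal(cca_max_bias(1, 0.2), abs(cca_bias(1, 0.2, 0.2)), tolerance = 1e-12)
  expect_equal(cca_max_bias(2, 0), 0)
  expect_equal(round(cca_max_bias(13.2, 0.471), 2), 9.93)
  pds <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(vapply(pds, cca_max_bias, numeric(1), sigma = 1)) > 0))
  for (pd in c(0.1, 0.2, 0.4)) {
    for (cc in seq(pd, 1, length.out = 8)) {
      expect_lte(abs(cca_bias(1, cc, pd)), cca_max_bias(1, pd) + 1e-12)
    }
  }
})

test_that("biases flip sign under direction reversal", {
  expect_equal(cca_bias(1.3, 0.4, 0.2, "higher"),
               -cca_bias(1.3, 0.4, 0.2, "lower"))
  mb_lo <- tm_max_bias(1, 1.5, 0.5, 0.2, "lower")
  mb_hi <- tm_max_bias(1, 1.5, 0.5, 0.2, "higher")
  expect_equal(mb_hi$tm_sm_max, -mb_lo$tm_sm_max)
  expect_equal(mb_hi$tm_total_max, -mb_lo$tm_total_max)
  lo <- combine_biases(0.3, 1.2, 1, dropout_scenario(0.2, 0.8), NULL, 0.5)
  hi <- combine_biases(0.3, 1.2, 1,
                       dropout_scenario(0.2, 0.8, direction = "higher"),
                       NULL, 0.5, direction = "higher")
  expect_equal(hi$b_ls, -lo$b_ls)
  expect_equal(hi$b_sm_arm0, -lo$b_sm_arm0)
})

test_that("maximum TM bias matches the adversarial-dropout oracle", {
  expect_equal(tm_max_bias(1, 1, 0.5, 0)$tm_sm_max, 0)
  mb <- tm_max_bias(1, 1.5, 0.5, 0.2)
  expect_equal(mb$tm_total_max, mb$tm_sm_max + location_shift_bias(1.5, 1, 0.5),
               tolerance = 1e-12)
  set.seed(74)
  oracle <- mc_tm_worst_bias(0.5, 0.2, n = 1e6)
  expect_equal(mb$tm_sm_max, oracle, tolerance = 0.01)
  expect_error(tm_max_bias(1, 1, 0.3, 0.5), "infeasible")
})

test_that("full-sample SD inference inverts homogeneous thinning", {
  expect_equal(infer_full_sd(13.2, 1, 0.523), 13.2)
  # fully directional: observed SD is a tail-truncated SD
  expect_equal(infer_full_sd(truncated_sd(2, 0.3, 1), 0.3, 0.3), 2,
               tolerance = 1e-10)
  # simulation round trip
  set.seed(75)
  n <- 1e6
  y <- rnorm(n, sd = 2)
  region <- order(y)[seq_len(0.6 * n)]
  y[sample(region, 0.2 * n)] <- NA
  expect_equal(infer_full_sd(sd(y, na.rm = TRUE), 0.6, 0.2), 2,
               tolerance = 0.01)
  expect_gt(infer_full_sd(3, 0.6, 0.2), infer_full_sd(2.9, 0.6, 0.2))
})

test_that("bias decompositions satisfy the published arithmetic identities", {
  a <- bias_decomposition(-8.26, -7.17, -10.36, 0)
  expect_equal(a$b_total, -17.53)
  expect_equal(round(a$bias_adjusted_estimate, 2), 9.27)
  expect_equal(a$estimate_bounds, c(-8.26, 9.27), tolerance = 1e-10)
  c_ <- bias_decomposition(-8.26, -2.01, -5.5, 0.41)
  expect_equal(round(c_$bias_adjusted_estimate, 2), -1.16)
  z <- bias_decomposition(0.42, 0, 0, 0)
  expect_equal(z$bias_adjusted_estimate, 0.42)
  expect_equal(z$estimate_bounds, c(0.42, 0.42))
})

test_that("combine_biases signs the per-arm components by arm and direction", {
  d <- combine_biases(0.69, 1, 1, dropout_scenario(0.2, 1), NULL, 0.5)
  expect_equal(d$b_ls, 0)
  expect_equal(round(d$b_sm_arm0, 2), 0.19) # comparator violation inflates
  expect_equal(d$b_sm_arm1, 0)
  expect_equal(round(d$bias_adjusted_estimate, 2), 0.50)
  # treatment-arm violation deflates under lower trimming
  d1 <- combine_biases(0, 1, 1, NULL, dropout_scenario(0.2, 1), 0.5)
  expect_lt(d1$b_sm_arm1, 0)
  expect_error(
    combine_biases(0, 1, 1, dropout_scenario(0.2, 1, direction = "higher"),
                   NULL, 0.5, direction = "lower"),
    "inconsistent")
})

test_that("closed-form decomposition predicts simulated means across spreads", {
  set.seed(76)
  S <- 120
  for (cc in c(0.5, 1)) {
    est <- replicate(S, {
      d <- generate_trial(trial_design(250, effect = 0.5, arm_sigmas = c(1.5, 1)))
      d <- apply_dropout(d, mech_restricted(0, 0.2, cc))
      tm_fit(d, trim_spec(0.5))$estimate
    })
    pred <- 0.5 + location_shift_bias(1, 1.5, 0.5) +
      strong_mnar_bias(1.5, 0.5, cc, 0.2)
    expect_lt(abs(mean(est) - pred), 3 * sd(est) / sqrt(S))
  }
})
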