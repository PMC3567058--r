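test_that("RDR estimation matches the analytic attenuation factor", {
  # repeat identical to baseline: RDR exactly 1
  set.seed(1)
  b <- rnorm(100)
  exact <- estimate_rdr(data.frame(baseline = b, repeat_meas = b),
                        adjust = character(0))
  expect_equal(exact$rdr, 1, tolerance = 1e-12)

  # classical error with equal usual and error variances: RDR about 0.5
  n <- 50000
  u <- rnorm(n)
  pairs <- data.frame(baseline = u + rnorm(n), repeat_meas = u + rnorm(n))
  est <- estimate_rdr(pairs, adjust = character(0))
  expect_equal(est$rdr, 0.5, tolerance = 0.02)
  expect_lt(est$ci_low, est$rdr)
  expect_gt(est$ci_high, est$rdr)

  expect_error(estimate_rdr(pairs[1:5, ], adjust = character(0)),
               "at least 10")
  expect_error(
    estimate_rdr(data.frame(baseline = rep(1, 20),
                            repeat_meas = rnorm(20)),
                 adjust = character(0)),
    "zero variance")
})

test_that("generator-calibrated RDR estimates hit the targets", {
  spec <- cohort_spec(n_participants = 20000, repeat_subsample_n = 8000,
                      seed = 33)
  coh <- generate_cohort(spec)
  for (m in seq_along(marker_names)) {
    pairs <- data.frame(baseline = coh[[paste0(marker_names[m], "_log_base")]],
                        repeat_meas = coh[[paste0(marker_names[m], "_log_rep")]],
                        age = coh$age, sex = coh$sex)
    est <- estimate_rdr(pairs[!is.na(pairs$repeat_meas), ])
    expect_equal(est$rdr, spec$target_rdrs[m], tolerance = 0.04)
  }
})

test_that("usual-level prediction shrinks toward the mean with slope RDR", {
  set.seed(2)
  n <- 5000
  u <- rnorm(n, 3, 1)
  b <- u + rnorm(n)
  pairs <- data.frame(baseline = b, repeat_meas = u + rnorm(n))
  est <- estimate_rdr(pairs, adjust = character(0))
  usual <- predict_usual_levels(est, data.frame(baseline = b))
  # closed form of simple-regression prediction, pointwise
  expect_equal(usual,
               mean(pairs$repeat_meas) + est$rdr * (b - mean(b)),
               tolerance = 1e-10)
  # variance identity var(pred) = rdr^2 var(baseline)
  expect_equal(var(usual), est$rdr^2 * var(b), tolerance = 1e-10)
  # affine equivariance: shifting baseline by c shifts predictions by rdr*c
  usual_shift <- predict_usual_levels(est, data.frame(baseline = b + 2))
  expect_equal(usual_shift - usual, rep(est$rdr * 2, n), tolerance = 1e-10)
  # rdr = 1 limit: usual equals baseline
  est1 <- estimate_rdr(data.frame(baseline = b, repeat_meas = b),
                       adjust = character(0))
  expect_equal(predict_usual_levels(est1, data.frame(baseline = b)), b,
               tolerance = 1e-10)
  expect_error(predict_usual_levels(est, data.frame(bad = 1)),
               "baseline")
})

test_that("correction recovers the true OR that the naive fit attenuates", {
  spec <- plain_spec(50000, beta = c(log(1.5), 0, 0), repeat_n = 10000,
                     seed = 44)
  coh <- generate_cohort(spec)
  z <- standardize_log_exposure(coh$tpa_log_base)$z
  naive <- fit_logistic_irls(cbind(1, z), coh$is_case)$coef[2]
  corr <- corrected_or_per_sd(coh, "tpa", covariates = character(0),
                              rdr_adjust = character(0),
                              ci_method = "naive")
  expect_lt(abs(log(corr$or) / log(1.5) - 1), 0.10)
  expect_lt(abs(naive / (0.5 * log(1.5)) - 1), 0.10)
})

test_that("RDR = 1 makes corrected and naive ORs coincide", {
  spec <- plain_spec(8000, rdrs = c(1, 1, 1), repeat_n = 4000, seed = 45)
  coh <- generate_cohort(spec)
  z <- standardize_log_exposure(coh$tpa_log_base)$z
  naive <- fit_logistic_irls(cbind(1, z), coh$is_case)$coef[2]
  corr <- corrected_or_per_sd(coh, "tpa", covariates = character(0),
                              rdr_adjust = character(0),
                              ci_method = "naive")
  expect_equal(log(corr$or), unname(naive), tolerance = 1e-8)
})

test_that("bootstrap CI is wider than the naive second-stage CI", {
  spec <- plain_spec(4000, beta = c(log(1.4), 0, 0), repeat_n = 300,
                     seed = 46)
  coh <- generate_cohort(spec)
  naive <- corrected_or_per_sd(coh, "tpa", covariates = character(0),
                               rdr_adjust = character(0),
                               ci_method = "naive")
  boot <- corrected_or_per_sd(coh, "tpa", covariates = character(0),
                              rdr_adjust = character(0),
                              ci_method = "bootstrap", n_boot = 200,
                              seed = 46)
  expect_gt(log(boot$ci_high) - log(boot$ci_low),
            log(naive$ci_high) - log(naive$ci_low))
  # bootstrap is reproducible under the same seed
  boot2 <- corrected_or_per_sd(coh, "tpa", covariates = character(0),
                               rdr_adjust = character(0),
                               ci_method = "bootstrap", n_boot = 200,
                               seed = 46)
  expect_equal(boot, boot2)
})

test_that("stability-versus-gap trend recovers a synthetic decay", {
  # constant estimates: slope exactly zero
  flat <- data.frame(estimate = rep(0.6, 5), se = rep(0.05, 5),
                     gap_years = 1:5)
  expect_equal(rdr_time_trend(flat)$slope, 0, tolerance = 1e-12)

  set.seed(3)
  gaps <- c(1, 2, 3, 5, 8, 11.6)
  est <- 0.9 - 0.03 * gaps + rnorm(6, 0, 0.005)
  tr <- rdr_time_trend(data.frame(estimate = est, se = rep(0.02, 6),
                                  gap_years = gaps))
  expect_lt(abs(tr$slope + 0.03), 0.005)
  expect_lt(tr$p, 0.01)

  # halving one SE quadruples that point's weight: check against direct WLS
  d <- data.frame(estimate = c(0.9, 0.7, 0.5, 0.65), se = c(0.1, 0.05, 0.1, 0.2),
                  gap_years = c(1, 4, 9, 6))
  tr2 <- rdr_time_trend(d)
  w <- 1 / d$se^2
  X <- cbind(1, d$gap_years)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * d$estimate))
  expect_equal(tr2$slope, beta[2], tolerance = 1e-10)

  expect_error(rdr_time_trend(flat[1:2, ]), "at least 3")
  expect_error(rdr_time_trend(transform(flat, gap_years = 2)), "equal")
})

test_that("two-stage correction is consistent in repeated cohorts", {
  # distributional check at reduced scale; the full-scale version of this
  # property (200 cohorts of 20,000) runs in the acceptance suite
  naive <- corrected <- numeric(30)
  for (s in 1:30) {
    spec <- plain_spec(15000, beta = c(log(1.3), 0, 0), repeat_n = 3000,
                       seed = 5000 + s)
    coh <- generate_cohort(spec)
    z <- standardize_log_exposure(coh$tpa_log_base)$z
    naive[s] <- fit_logistic_irls(cbind(1, z), coh$is_case)$coef[2]
    corrected[s] <- log(corrected_or_per_sd(
      coh, "tpa", covariates = character(0), rdr_adjust = character(0),
      ci_method = "naive")$or)
  }
  expect_lt(abs(mean(naive) / (0.5 * log(1.3)) - 1), 0.10)
  expect_lt(abs(mean(corrected) / log(1.3) - 1), 0.10)
})
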