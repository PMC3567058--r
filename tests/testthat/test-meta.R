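test_that("extreme-quantile spacing matches numeric integration", {
  d_numeric <- function(q) {
    zq <- qnorm(1 - q)
    top <- integrate(function(x) x * dnorm(x), zq, Inf)$value / q
    2 * top  # symmetry: bottom-group mean is -top
  }
  for (q in c(1/2, 1/3, 1/4, 1/5, 0.1)) {
    expect_equal(quantile_spacing(q), d_numeric(q), tolerance = 1e-6)
  }
  expect_equal(quantile_spacing(1/2), 4 * dnorm(0), tolerance = 1e-12)
  # strictly increasing as the extreme fraction shrinks
  qs <- c(1/2, 1/3, 1/4, 1/5, 1/10)
  expect_true(all(diff(quantile_spacing(qs)) > 0))
  expect_error(quantile_spacing(0.6), "q must")
  expect_error(quantile_spacing(0), "q must")
})

test_that("CI inversion recovers the standard error of the log RR", {
  b <- 0.22; s <- 0.031
  expect_equal(se_from_ci(exp(b), exp(b - 1.96 * s), exp(b + 1.96 * s)), s,
               tolerance = 1e-12)
  expect_equal(se_from_ci(1.25, 1.18, 1.33),
               (log(1.33) - log(1.18)) / 3.92, tolerance = 1e-12)
  expect_warning(se_from_ci(1.2, 1.2, 1.2), "degenerate")
  expect_error(se_from_ci(1.2, -1, 1.3), "positive")
})

test_that("harmonization converts each native form to the per-SD scale", {
  per_sd <- data.frame(study = "a", marker = "m", form = "per_sd",
                       q = NA, rr = 1.3, ci_low = 1.1, ci_high = 1.54,
                       sd = NA)
  h <- harmonize_to_per_sd(per_sd)
  expect_equal(h$log_rr_per_sd, log(1.3))

  eq <- data.frame(study = "b", marker = "m", form = "extreme_quantiles",
                   q = 1/5, rr = 2.0, ci_low = 1.5, ci_high = 2.67, sd = NA)
  he <- harmonize_to_per_sd(eq)
  expect_equal(exp(he$log_rr_per_sd), exp(log(2) / quantile_spacing(1/5)))
  expect_equal(exp(he$log_rr_per_sd), 1.281, tolerance = 1e-3)

  pu <- data.frame(study = "c", marker = "m", form = "per_unit",
                   q = NA, rr = 1.1, ci_low = 1.05, ci_high = 1.15, sd = 2)
  expect_equal(exp(harmonize_to_per_sd(pu)$log_rr_per_sd), 1.1^2,
               tolerance = 1e-12)
  pu$sd <- NA
  expect_error(harmonize_to_per_sd(pu), "requires the study SD")
})

test_that("harmonization round-trips the simulator's native forms exactly", {
  est <- generate_study_estimates(24, true_log_rr_per_sd = 0.2,
                                  tau2 = 0.02, seed = 5)
  h <- harmonize_to_per_sd(est)
  # invert the harmonization per-form and compare bit-for-bit
  for (i in seq_len(nrow(est))) {
    scale <- switch(est$form[i],
                    per_sd = 1,
                    extreme_quantiles = quantile_spacing(est$q[i]),
                    per_unit = ,
                    per_log_unit = 1 / est$sd[i])
    expect_equal(h$log_rr_per_sd[i] * scale, log(est$rr[i]),
                 tolerance = 1e-12)
  }
})

test_that("DerSimonian-Laird pooling matches hand-computed values", {
  p <- pool_random_effects(c(0, 2), c(1, 1))
  expect_equal(p$Q, 2)
  expect_equal(p$tau2, 1)
  expect_equal(p$pooled, 1)
  expect_equal(p$se, 1)
  expect_equal(p$i2, 50)

  # identical effects: no heterogeneity at all
  p0 <- pool_random_effects(rep(0.3, 4), rep(0.1, 4))
  expect_equal(p0$pooled, 0.3)
  expect_equal(p0$Q, 0)
  expect_equal(p0$tau2, 0)
  expect_equal(p0$i2, 0)
})

test_that("DL pooling matches an independent reimplementation and metafor", {
  set.seed(16)
  for (r in 1:10) {
    k <- sample(3:15, 1)
    y <- rnorm(k, 0.2, 0.3)
    se <- runif(k, 0.05, 0.4)
    p <- pool_random_effects(y, se)
    o <- dl_oracle(y, se)
    expect_equal(p$pooled, o$pooled, tolerance = 1e-12)
    expect_equal(p$tau2, o$tau2, tolerance = 1e-12)
    expect_equal(p$se, o$se, tolerance = 1e-12)
    expect_equal(p$i2, o$i2, tolerance = 1e-12)
    # pooled estimate stays inside the convex hull of the effects
    expect_gte(p$pooled, min(y))
    expect_lte(p$pooled, max(y))
  }
  y <- c(0.05, 0.18, 0.30, 0.12, 0.44)
  se <- c(0.08, 0.12, 0.20, 0.05, 0.25)
  p <- pool_random_effects(y, se)
  m <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(p$pooled, as.numeric(m$beta), tolerance = 1e-8)
  expect_equal(p$tau2, m$tau2, tolerance = 1e-8)
  expect_equal(p$se, m$se, tolerance = 1e-8)
})

test_that("tau2 = 0 reduces random-effects pooling to fixed-effect", {
  y <- c(0.1, 0.1, 0.1)
  se <- c(0.1, 0.2, 0.3)
  p <- pool_random_effects(y, se)
  w <- 1 / se^2
  expect_equal(p$tau2, 0)
  expect_equal(p$pooled, sum(w * y) / sum(w))
  expect_equal(p$se, sqrt(1 / sum(w)))
})

test_that("I2 is invariant when y and se share a common rescaling", {
  set.seed(17)
  y <- rnorm(8, 0.2, 0.2)
  se <- runif(8, 0.05, 0.3)
  p1 <- pool_random_effects(y, se)
  p2 <- pool_random_effects(3 * y, 3 * se)
  expect_equal(p1$i2, p2$i2, tolerance = 1e-10)
  expect_equal(p1$Q, p2$Q, tolerance = 1e-10)
})

test_that("meta-regression recovers noiseless slopes and WLS identities", {
  x <- c(1, 2, 3, 4, 5)
  y <- 0.1 + 0.05 * x
  se <- rep(0.1, 5)
  mr <- meta_regress(y, se, x)
  expect_equal(mr$slope, 0.05, tolerance = 1e-10)
  expect_equal(mr$tau2, 0, tolerance = 1e-10)

  # binary covariate with tau2 = 0: slope equals the difference of the
  # subgroup fixed-effect means
  g <- c(0, 0, 0, 1, 1, 1)
  y2 <- c(0.1, 0.12, 0.11, 0.3, 0.31, 0.29)
  se2 <- c(0.1, 0.2, 0.15, 0.1, 0.2, 0.15)
  mr2 <- meta_regress(y2, se2, g)
  if (mr2$tau2 == 0) {
    w <- 1 / se2^2
    m0 <- sum((w * y2)[g == 0]) / sum(w[g == 0])
    m1 <- sum((w * y2)[g == 1]) / sum(w[g == 1])
    expect_equal(mr2$slope, m1 - m0, tolerance = 1e-10)
  }
  expect_error(meta_regress(y[1:2], se[1:2], x[1:2]), "at least 3")
  expect_error(meta_regress(y, se, rep(1, 5)), "constant")
})

test_that("Egger's test satisfies its algebraic identities", {
  se <- c(0.05, 0.1, 0.2, 0.3, 0.15)
  # constant effect: intercept exactly 0, slope exactly the effect
  e0 <- egger_test(rep(0.25, 5), se)
  expect_equal(e0$intercept, 0, tolerance = 1e-10)
  expect_equal(e0$slope, 0.25, tolerance = 1e-10)
  # y = c + k * se: intercept exactly k
  e1 <- egger_test(0.1 + 1.7 * se, se)
  expect_equal(e1$intercept, 1.7, tolerance = 1e-10)
  expect_equal(e1$df, 3)
  expect_error(egger_test(c(0.1, 0.2), c(0.1, 0.1)), "at least 3")
})

test_that("Egger's test detects simulated small-study inflation", {
  set.seed(18)
  rej <- vapply(1:100, function(r) {
    est <- generate_study_estimates(15, true_log_rr_per_sd = 0.1,
                                    tau2 = 0.001, bias = 1.5,
                                    se_range = c(0.02, 0.3),
                                    forms = "per_sd", seed = 9000 + r)
    h <- harmonize_to_per_sd(est)
    egger_test(h$log_rr_per_sd, h$se)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.3)  # well above the nominal 5% false-positive rate
})

test_that("subgroup comparison behaves under equality and separation", {
  y <- c(0.2, 0.25, 0.18, 0.2, 0.25, 0.18)
  se <- rep(0.1, 6)
  g <- rep(c("a", "b"), each = 3)
  eq <- subgroup_compare(y, se, g)
  expect_equal(eq$z, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1, tolerance = 1e-12)

  set.seed(19)
  y2 <- c(rnorm(5, 0, 0.05), rnorm(5, 0.3, 0.05))
  se2 <- rep(0.05, 10)
  g2 <- rep(c("small", "large"), each = 5)
  sep <- subgroup_compare(y2, se2, g2)
  expect_lt(sep$p, 0.01)
  # union pooling lies between the subgroup estimates when tau2 = 0
  y3 <- c(0.1, 0.1, 0.3, 0.3)
  se3 <- rep(0.2, 4)
  un <- pool_random_effects(y3, se3)
  expect_gte(un$pooled, 0.1)
  expect_lte(un$pooled, 0.3)
  expect_error(subgroup_compare(y, se, rep("a", 6)), "2 levels")
})

test_that("study-estimate simulator gives calibrated pooled coverage", {
  covered <- vapply(1:60, function(r) {
    est <- generate_study_estimates(30, true_log_rr_per_sd = 0.15,
                                    tau2 = 0, bias = 0,
                                    se_range = c(0.05, 0.05),
                                    forms = "per_sd", seed = 100 + r)
    h <- harmonize_to_per_sd(est)
    p <- pool_random_effects(h$log_rr_per_sd, h$se)
    abs(p$pooled - 0.15) < 2 * p$se
  }, logical(1))
  expect_gt(mean(covered), 0.85)

  # DL tau2 is a usable estimate of the generating between-study variance
  tau2s <- vapply(1:40, function(r) {
    est <- generate_study_estimates(50, true_log_rr_per_sd = 0.1,
                                    tau2 = 0.04, se_range = c(0.05, 0.15),
                                    forms = "per_sd", seed = 200 + r)
    h <- harmonize_to_per_sd(est)
    pool_random_effects(h$log_rr_per_sd, h$se)$tau2
  }, numeric(1))
  expect_lt(abs(mean(tau2s) / 0.04 - 1), 0.5)
  expect_error(generate_study_estimates(0), "at least 1")
  expect_error(generate_study_estimates(5, tau2 = -1), "non-negative")
})

test_that("estimate CSV round-trips through the declared header", {
  est <- generate_study_estimates(8, seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates_csv(est, path)
  back <- read_estimates_csv(path)
  expect_equal(back$rr, est$rr)
  expect_identical(back$form, est$form)
  expect_equal(back$sd, est$sd)
})
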