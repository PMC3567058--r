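# shared fixtures and independent oracles for the test suite

marker_names <- c("tpa", "ddimer", "vwf")
covariate_names <- c("age", "male", "smoking", "diabetes", "bmi", "sbp",
                     "tchol", "log_tg")

zero_assoc <- function() {
  matrix(0, 3, 8, dimnames = list(marker_names, covariate_names))
}

zero_covariate_ors <- function() {
  stats::setNames(rep(0, 8), covariate_names)
}

# cohort spec with no covariate confounding: events depend on usual marker
# levels only
plain_spec <- function(n, beta = c(log(1.3), 0, 0), rdrs = c(0.5, 0.5, 0.5),
                       repeat_n = 2000, risk = 0.1, seed = 1) {
  cohort_spec(n_participants = n, true_log_or_per_sd = beta,
              target_rdrs = rdrs, covariate_log_ors = zero_covariate_ors(),
              marker_covariate_assoc = zero_assoc(),
              repeat_subsample_n = repeat_n, baseline_risk = risk,
              seed = seed)
}

# quick logistic dataset: z ~ N(0,1), optional categorical modifier,
# logit p = b0 + b1 z + b_int z [mod == top level]
sim_logistic_data <- function(n, b0 = -1, b1 = 0.3, b_int = 0,
                              n_mod_levels = 3) {
  z <- rnorm(n)
  mod <- sample.int(n_mod_levels, n, replace = TRUE)
  lp <- b0 + b1 * z + b_int * z * (mod == n_mod_levels)
  data.frame(marker = z, modifier = mod,
             is_case = rbinom(n, 1, plogis(lp)))
}

# independent maximum-likelihood oracle for logistic regression: direct
# BFGS maximization of the binomial log-likelihood with analytic gradient
logistic_ml_oracle <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    mu <- plogis(drop(X %*% b))
    -drop(crossprod(X, y - mu))
  }
  stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))$par
}

# independent DerSimonian-Laird implementation, loop-based
dl_oracle <- function(y, se) {
  k <- length(y)
  w <- sw <- sw2 <- swy <- 0
  wi <- numeric(k)
  for (i in 1:k) {
    wi[i] <- 1 / se[i]^2
    sw <- sw + wi[i]; sw2 <- sw2 + wi[i]^2; swy <- swy + wi[i] * y[i]
  }
  ybar <- swy / sw
  Q <- 0
  for (i in 1:k) Q <- Q + wi[i] * (y[i] - ybar)^2
  tau2 <- (Q - (k - 1)) / (sw - sw2 / sw)
  if (tau2 < 0) tau2 <- 0
  num <- den <- 0
  for (i in 1:k) {
    ws <- 1 / (se[i]^2 + tau2)
    num <- num + ws * y[i]; den <- den + ws
  }
  list(pooled = num / den, se = sqrt(1 / den), tau2 = tau2, Q = Q,
       i2 = max(0, 100 * (Q - (k - 1)) / Q))
}

# KL divergence between N(0, V) and N(0, diag(f[-1]) + f[1] J), written
# directly from the definition (dense solve, no Sherman-Morrison)
float_kl_direct <- function(f, V) {
  k <- nrow(V)
  FF <- diag(f[-1], k) + f[1]
  0.5 * (sum(diag(solve(FF) %*% V)) +
           as.numeric(determinant(FF)$modulus) -
           as.numeric(determinant(V)$modulus) - k)
}

# dense grid-search minimizer of the floated-variance KL objective, with
# iterative refinement of a log-spaced grid around the running optimum
float_grid_oracle <- function(V, n_points = 9, rounds = 18) {
  off <- V[upper.tri(V)]
  f0 <- max(mean(off), 1e-3 * max(diag(V)))
  center <- c(f0, pmax(diag(V) - f0, 1e-3 * max(diag(V))))
  width <- 3
  for (r in seq_len(rounds)) {
    grids <- lapply(center, function(c0)
      exp(seq(log(c0 / width), log(c0 * width), length.out = n_points)))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, float_kl_direct, V = V)
    i <- which.min(vals)
    on_boundary <- any(vapply(seq_along(grids), function(j)
      pts[i, j] <= grids[[j]][1] * 1.0001 ||
        pts[i, j] >= grids[[j]][n_points] * 0.9999, logical(1)))
    center <- pts[i, ]
    if (!on_boundary) width <- width^0.6
  }
  list(f = unname(center), value = float_kl_direct(center, V))
}

# random contrast covariance with a positive shared component, the shape
# produced by grouped logistic fits against a common reference group (the
# shared component is the reference coefficient's variance)
random_contrast_cov <- function(k = 3, sd = 0.3, common = 0.4) {
  A <- matrix(rnorm(k * k, sd = sd), k, k)
  0.3 * crossprod(A) + common * matrix(1, k, k) + diag(0.05, k)
}

# expand 2x2 case-control counts into unit records
expand_2x2 <- function(cases_exposed, cases_unexposed, controls_exposed,
                       controls_unexposed) {
  data.frame(
    exposed = rep(c(1, 0, 1, 0),
                  c(cases_exposed, cases_unexposed, controls_exposed,
                    controls_unexposed)),
    is_case = rep(c(1, 1, 0, 0),
                  c(cases_exposed, cases_unexposed, controls_exposed,
                    controls_unexposed)))
}
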