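ESTIMATE_CSV_HEADER <- c(
  "study", "marker", "form", "q", "rr", "ci_low", "ci_high", "n_cases",
  "adjustment_degree", "location", "specimen", "storage_c", "followup_y",
  "baseline_year")

#' Expected SD spacing between extreme quantile groups of a normal variable
#'
#' For a normally distributed exposure, the expected difference in means
#' between the top and bottom q-fractions is
#' \eqn{d_q = 2 \phi(\Phi^{-1}(1-q)) / q} standard deviations.  This is the
#' constant used to convert extreme-quantile risk ratios (top vs bottom
#' third, quarter or fifth) to a per-1-SD scale: about 2.18 for thirds,
#' 2.54 for quarters and 2.80 for fifths.
#'
#' @param q fraction in each extreme group, 0 < q <= 1/2.
#' @return spacing in SD units.
#' @export
quantile_spacing <- function(q) {
  if (any(q <= 0) || any(q > 0.5)) stop("q must lie in (0, 1/2]")
  2 * dnorm(qnorm(1 - q)) / q
}

#' Standard error of a log risk ratio from its 95\% CI
#'
#' @param rr point estimate (ratio scale).
#' @param ci_low,ci_high 95\% confidence limits (ratio scale).
#' @return SE of log(rr); a zero-width CI gives se = 0 with a warning.
#' @export
se_from_ci <- function(rr, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high <= 0) || any(rr <= 0))
    stop("rr and confidence limits must be positive")
  if (any(ci_high < ci_low)) stop("ci_high must be >= ci_low")
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  if (any(se == 0)) warning("degenerate CI with zero width (se = 0)")
  se
}

#' Harmonize published risk estimates to a common per-1-SD scale
#'
#' Converts each study's native effect form to a log risk ratio per 1 SD
#' higher marker level: \code{per_sd} estimates pass through unchanged;
#' \code{extreme_quantiles} estimates (top vs bottom q-fraction) are divided
#' by the normal-theory spacing \code{\link{quantile_spacing}(q)};
#' \code{per_unit} and \code{per_log_unit} estimates are multiplied by the
#' study's SD on the corresponding analysis scale.
#'
#' @param estimates data.frame of published estimates with columns
#'   \code{study}, \code{marker}, \code{form}, \code{q}, \code{rr},
#'   \code{ci_low}, \code{ci_high} (and \code{sd} where the form needs it).
#' @param sd optional vector overriding the \code{sd} column.
#' @return data.frame: study, marker, log_rr_per_sd, se.
#' @export
harmonize_to_per_sd <- function(estimates, sd = NULL) {
  y <- log(estimates$rr)
  se <- se_from_ci(estimates$rr, estimates$ci_low, estimates$ci_high)
  if (is.null(sd)) sd <- estimates$sd
  scale <- vapply(seq_len(nrow(estimates)), function(i) {
    form <- estimates$form[i]
    switch(form,
           per_sd = 1,
           extreme_quantiles = 1 / quantile_spacing(estimates$q[i]),
           per_unit = ,
           per_log_unit = {
             if (is.null(sd) || is.na(sd[i]))
               stop("form '", form, "' requires the study SD (row ", i, ")")
             sd[i]
           },
           stop("unknown effect form: ", form))
  }, numeric(1))
  data.frame(study = estimates$study, marker = estimates$marker,
             log_rr_per_sd = y * scale, se = se * scale,
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments estimate of the between-study variance:
#' with fixed weights \eqn{w_i = 1/se_i^2}, \eqn{Q = \sum w_i (y_i - \bar
#' y_w)^2} and \eqn{\tau^2 = \max(0, (Q - df) / (\sum w - \sum w^2/\sum w))};
#' the pooled estimate uses random-effects weights
#' \eqn{w_i^* = 1/(se_i^2 + \tau^2)}.  Heterogeneity is summarised by Q, its
#' chi-square p-value, and \eqn{I^2 = \max(0, 100 (Q - df)/Q)}.
#'
#' @param y log risk ratios (per 1 SD).
#' @param se their standard errors (all > 0).
#' @param method \code{"DL"} (default) or \code{"REML"} (Fisher-scoring
#'   profile likelihood).
#' @return object of class \code{pooled_result}: list with \code{pooled},
#'   \code{se}, \code{ci_low}, \code{ci_high} (log scale), \code{tau2},
#'   \code{Q}, \code{df}, \code{p_heterogeneity}, \code{i2}, \code{k}.
#' @export
pool_random_effects <- function(y, se, method = c("DL", "REML")) {
  method <- match.arg(method)
  if (length(y) < 2) stop("need at least 2 studies")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df <- length(y) - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  if (method == "REML") {
    tau2 <- reml_tau2(y, se, start = tau2)
  }
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * y) / sum(wr)
  se_pooled <- sqrt(1 / sum(wr))
  i2 <- max(0, 100 * (Q - df) / Q)
  structure(list(pooled = pooled, se = se_pooled,
                 ci_low = pooled - 1.96 * se_pooled,
                 ci_high = pooled + 1.96 * se_pooled,
                 tau2 = tau2, Q = Q, df = df,
                 p_heterogeneity = pchisq(Q, df, lower.tail = FALSE),
                 i2 = i2, k = length(y), method = method),
            class = "pooled_result")
}

# restricted maximum likelihood tau^2 by direct 1-d optimization of the
# restricted log-likelihood (intercept-only model)
reml_tau2 <- function(y, se, start = 0) {
  nll <- function(t2) {
    v <- se^2 + t2
    w <- 1 / v
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  stats::optimize(nll, c(0, max(start * 10, var(y) * 10, 1e-3)))$minimum
}

#' Random-effects meta-regression on a study-level covariate
#'
#' Method-of-moments between-study variance from the residual heterogeneity
#' of the fixed-effects meta-regression, then weighted least squares with
#' weights \eqn{1/(se^2 + \tau^2)} and a two-sided z-test on the slope.
#'
#' @param y log risk ratios per 1 SD.
#' @param se their standard errors.
#' @param covariate study-level covariate (numeric, or coercible binary).
#' @return list with \code{slope}, \code{se}, \code{z}, \code{p},
#'   \code{tau2}, \code{intercept}.
#' @export
meta_regress <- function(y, se, covariate) {
  if (length(y) < 3) stop("need at least 3 studies")
  x <- as.numeric(covariate)
  if (length(unique(x)) < 2) stop("covariate is constant across studies")
  X <- cbind(1, x)
  W <- diag(1 / se^2)
  XtWX_inv <- solve(t(X) %*% W %*% X)
  H <- X %*% XtWX_inv %*% t(X) %*% W
  r <- y - drop(H %*% y)
  QE <- sum(r^2 / se^2)
  p <- ncol(X)
  # E[QE] = (k - p) + tau2 * (sum(w) - tr((X'WX)^-1 X'W^2 X))
  trP <- sum(diag(W)) - sum(diag(XtWX_inv %*% (t(X) %*% W %*% W %*% X)))
  tau2 <- max(0, (QE - (length(y) - p)) / trP)
  Wr <- diag(1 / (se^2 + tau2))
  V <- solve(t(X) %*% Wr %*% X)
  beta <- unname(drop(V %*% t(X) %*% Wr %*% y))
  slope_se <- sqrt(V[2, 2])
  z <- beta[2] / slope_se
  list(slope = beta[2], se = slope_se, z = z, p = 2 * pnorm(-abs(z)),
       tau2 = tau2, intercept = beta[1])
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Classical unweighted form: ordinary least squares of the standardized
#' effect \eqn{y_i/se_i} on precision \eqn{1/se_i}; the intercept measures
#' asymmetry and is tested with a t-test on n - 2 degrees of freedom.
#'
#' @param y log risk ratios per 1 SD.
#' @param se their standard errors.
#' @return object of class \code{egger_result}: list with \code{intercept},
#'   \code{se}, \code{t}, \code{df}, \code{p}, \code{slope}.
#' @export
egger_test <- function(y, se) {
  if (length(y) < 3) stop("Egger's test needs at least 3 studies")
  fit <- lm(I(y / se) ~ I(1 / se))
  b <- coef(fit)
  sb <- suppressWarnings(sqrt(diag(vcov(fit))))  # exact fits give se ~ 0
  tval <- b[1] / sb[1]
  df <- length(y) - 2
  structure(list(intercept = unname(b[1]), se = unname(sb[1]),
                 t = unname(tval), df = df,
                 p = unname(2 * pt(-abs(tval), df)), slope = unname(b[2])),
            class = "egger_result")
}

#' Compare pooled estimates between two study subgroups
#'
#' Pools each subgroup by random-effects meta-analysis and tests the
#' difference of pooled log risk ratios with a two-sided z-test treating the
#' subgroups as independent.
#'
#' @param y,se harmonized effects and standard errors.
#' @param group logical or two-level vector splitting the studies
#'   (e.g. \code{n_cases >= 500}).
#' @return list with per-group \code{pooled_result}s (\code{groups}),
#'   \code{diff}, \code{z}, \code{p}.
#' @export
subgroup_compare <- function(y, se, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("grouping must have exactly 2 levels")
  if (any(table(g) < 2)) stop("each subgroup needs at least 2 studies")
  pools <- lapply(levels(g), function(l)
    pool_random_effects(y[g == l], se[g == l]))
  names(pools) <- levels(g)
  diff <- pools[[1]]$pooled - pools[[2]]$pooled
  zse <- sqrt(pools[[1]]$se^2 + pools[[2]]$se^2)
  z <- diff / zse
  list(groups = pools, diff = diff, z = z, p = 2 * pnorm(-abs(z)))
}

#' Simulate a set of published study estimates
#'
#' Draws per-SD true study effects from a random-effects model
#' \eqn{y_i \sim N(\mu + bias \cdot se_i,\; se_i^2 + \tau^2)} and converts
#' each into a native reporting form (per SD, extreme quantiles, per unit or
#' per log unit) by inverting the harmonization transform, so that
#' \code{\link{harmonize_to_per_sd}} round-trips exactly.  \code{bias > 0}
#' emulates small-study effects (inflated estimates in less precise
#' studies).
#'
#' @param k number of studies.
#' @param true_log_rr_per_sd common true effect on the per-SD log scale.
#' @param tau2 between-study variance.
#' @param bias small-study inflation of the mean per unit of se.
#' @param se_range range of per-SD standard errors (uniform draw).
#' @param forms effect forms to cycle through.
#' @param q extreme-group fraction used for extreme_quantiles forms.
#' @param seed integer seed.
#' @return data.frame of published estimates (see
#'   \code{\link{harmonize_to_per_sd}}), including study covariates and the
#'   per-study \code{sd} needed to undo unit-based forms.
#' @export
generate_study_estimates <- function(k, true_log_rr_per_sd = 0.15,
                                     tau2 = 0.01, bias = 0,
                                     se_range = c(0.03, 0.25),
                                     forms = c("per_sd", "extreme_quantiles",
                                               "per_unit", "per_log_unit"),
                                     q = 1 / 5, seed = 1L) {
  if (k < 1) stop("k must be at least 1")
  if (tau2 < 0) stop("tau2 must be non-negative")
  with_substream(seed, "study-estimates", {
    se <- runif(k, se_range[1], se_range[2])
    y <- rnorm(k, true_log_rr_per_sd + bias * se, sqrt(se^2 + tau2))
    form <- rep_len(forms, k)
    sd_study <- exp(runif(k, log(0.3), log(1.5)))
    scale <- ifelse(form == "extreme_quantiles", quantile_spacing(q),
                    ifelse(form %in% c("per_unit", "per_log_unit"),
                           1 / sd_study, 1))
    y_native <- y * scale
    se_native <- se * scale
    data.frame(
      study = sprintf("study_%02d", seq_len(k)),
      marker = "marker", form = form,
      q = ifelse(form == "extreme_quantiles", q, NA_real_),
      rr = exp(y_native),
      ci_low = exp(y_native - 1.96 * se_native),
      ci_high = exp(y_native + 1.96 * se_native),
      n_cases = round(exp(runif(k, log(70), log(3000)))),
      adjustment_degree = sample(1:4, k, replace = TRUE),
      location = sample(c("USA", "UK", "Europe", "Other"), k, replace = TRUE),
      specimen = sample(c("plasma", "serum"), k, replace = TRUE,
                        prob = c(0.8, 0.2)),
      storage_c = sample(c(-20, -40, -70, -80, -196), k, replace = TRUE),
      followup_y = round(runif(k, 2.4, 19.4), 1),
      baseline_year = sample(1976:2002, k, replace = TRUE),
      sd = sd_study, stringsAsFactors = FALSE)
  })
}

#' Write / read published-estimate tables as CSV
#'
#' @param estimates estimate data.frame.
#' @param path file path.
#' @export
write_estimates_csv <- function(estimates, path) {
  cols <- c(ESTIMATE_CSV_HEADER, intersect("sd", names(estimates)))
  utils::write.csv(estimates[, cols], path, row.names = FALSE, na = "")
}

#' @rdname write_estimates_csv
#' @return \code{read_estimates_csv}: estimate data.frame.
#' @export
read_estimates_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ESTIMATE_CSV_HEADER, names(d))
  if (length(missing_cols) > 0)
    stop("estimate CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  d
}
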