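#' Group subjects by quantiles of the control distribution
#'
#' Cut-points are empirical percentiles of the control values (linear
#' interpolation of the empirical CDF, R quantile type 7); all subjects,
#' cases and controls alike, are assigned by those cut-points, with ties
#' going to the lower group.  For fifths the cut-points sit at the
#' 20/40/60/80 percentiles of controls.
#'
#' @param values log-scale marker values for all subjects.
#' @param control_values values among controls (defines the cut-points).
#' @param n_groups number of groups (default 5, i.e. fifths).
#' @return object of class \code{quantile_grouping}: list with
#'   \code{cutpoints}, \code{group} (integer 1..n_groups per subject) and
#'   \code{geometric_mean} of the original-scale marker per group.
#' @export
quantile_grouping <- function(values, control_values = values, n_groups = 5) {
  control_values <- control_values[!is.na(control_values)]
  if (length(unique(control_values)) < n_groups)
    stop("need at least ", n_groups, " distinct control values")
  probs <- seq_len(n_groups - 1) / n_groups
  cuts <- unname(quantile(control_values, probs, type = 7))
  group <- 1L + rowSums(outer(values, cuts, ">"))
  gm <- vapply(seq_len(n_groups),
               function(g) exp(mean(values[group == g])), numeric(1))
  structure(list(cutpoints = cuts, group = as.integer(group),
                 geometric_mean = gm, n_groups = n_groups),
            class = "quantile_grouping")
}

#' Logistic model with quantile-group indicators
#'
#' Fits case status on indicators for groups 2..K (bottom group reference)
#' plus adjustment covariates, returning the indicator coefficients (log
#' odds ratios versus the bottom group) and their covariance block.
#'
#' @param data case-control table with \code{is_case}.
#' @param grouping a \code{\link{quantile_grouping}} aligned with
#'   \code{data} rows.
#' @param covariates adjustment covariate names.
#' @return list with \code{contrasts} (K-1 log-ORs), \code{cov} (their
#'   covariance matrix), \code{n_cases}/\code{n_controls} per group, and the
#'   underlying \code{fit}.
#' @export
fit_quantile_group_model <- function(data, grouping, covariates = character(0)) {
  g <- grouping$group
  K <- grouping$n_groups
  n_cases <- vapply(seq_len(K), function(k) sum(g == k & data$is_case == 1),
                    numeric(1))
  n_controls <- vapply(seq_len(K), function(k) sum(g == k & data$is_case == 0),
                       numeric(1))
  empty <- which(n_cases == 0 | n_controls == 0)
  if (length(empty) > 0)
    stop("group(s) ", paste(empty, collapse = ", "),
         " contain no cases or no controls")
  ind <- outer(g, 2:K, "==") * 1
  colnames(ind) <- paste0("fifth", 2:K)
  X <- cbind(`(Intercept)` = 1, ind, covariate_design(data, covariates))
  fit <- fit_logistic_irls(X, data$is_case)
  idx <- colnames(ind)
  list(contrasts = fit$coef[idx], cov = fit$vcov[idx, idx],
       n_cases = n_cases, n_controls = n_controls, fit = fit)
}

# KL divergence between N(0, V) and the floated independence approximation
# N(0, F) with F = diag(f[-1]) + f[1] * J, plus its gradient in log f.
# Sherman-Morrison keeps the inverse cheap.
float_kl_objective <- function(logf, V) {
  f <- exp(logf)
  f0 <- f[1]; d <- f[-1]
  k <- length(d)
  Dinv <- 1 / d
  denom <- 1 + f0 * sum(Dinv)
  Finv <- diag(Dinv, k) - (f0 / denom) * tcrossprod(Dinv)
  logdetF <- sum(log(d)) + log(denom)
  logdetV <- determinant(V, logarithm = TRUE)$modulus
  kl <- 0.5 * (sum(Finv * V) + logdetF - as.numeric(logdetV) - k)
  G <- 0.5 * (Finv - Finv %*% V %*% Finv)
  grad <- c(sum(G), diag(G)) * f
  list(value = kl, grad = grad)
}

#' Floated variances for grouped log odds ratios
#'
#' Computes per-group "floated" variances in the sense of floating absolute
#' risk: positive numbers \eqn{f_0, f_1, \ldots, f_{K-1}} such that the
#' variance of any between-group contrast of log-ORs is approximated by the
#' sum of the two groups' floated variances.  Following the
#' divergence-based refinement of the method, f minimizes the Kullback-
#' Leibler divergence between the true contrast distribution N(0, V) and
#' the independence approximation N(0, F) with
#' \eqn{F = diag(f_1..f_{K-1}) + f_0 J}.  Minimization is quasi-Newton (BFGS)
#' on log f with analytic gradient, initialized from the heuristic
#' \eqn{f_0 = } mean off-diagonal covariance, \eqn{f_j = V_{jj} - f_0}.
#'
#' @param contrast_cov (K-1)x(K-1) covariance matrix of the log-OR contrasts
#'   versus the reference group, K >= 3.
#' @return object of class \code{floated_variances}: list with \code{f}
#'   (length K, reference group first), \code{kl_divergence} (nats),
#'   \code{se_ratio_range} (min/max of approximated over true contrast SE
#'   across all group pairs), and \code{converged}.
#' @export
float_variances <- function(contrast_cov) {
  V <- as.matrix(contrast_cov)
  k <- nrow(V)
  if (k < 2)
    stop("K = 2 groups is underdetermined: only f_0 + f_1 is identified")
  if (max(abs(V - t(V))) > 1e-8) stop("contrast covariance must be symmetric")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("contrast covariance is not positive definite")

  off <- V[upper.tri(V)]
  f0_init <- if (length(off) > 0) max(mean(off), 1e-4 * max(diag(V)))
             else 0.5 * min(diag(V))
  d_init <- pmax(diag(V) - f0_init, 1e-4 * max(diag(V)))
  init <- log(c(f0_init, d_init))

  opt <- stats::optim(init,
                      fn = function(p) float_kl_objective(p, V)$value,
                      gr = function(p) float_kl_objective(p, V)$grad,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  f <- exp(opt$par)
  if (opt$convergence != 0)
    stop("floated-variance optimization failed to converge (code ",
         opt$convergence, ")")

  # SE ratios over all pairs, including pairs with the reference group
  ratios <- c(sqrt((f[1] + f[-1]) / diag(V)))
  if (k >= 2) {
    for (j in seq_len(k - 1)) for (l in (j + 1):k) {
      true_var <- V[j, j] + V[l, l] - 2 * V[j, l]
      ratios <- c(ratios, sqrt((f[j + 1] + f[l + 1]) / true_var))
    }
  }
  structure(list(f = unname(f), kl_divergence = opt$value,
                 se_ratio_range = range(ratios), converged = TRUE),
            class = "floated_variances")
}

#' Per-group odds ratios with floated confidence intervals
#'
#' Every group, including the reference (log-OR fixed at 0), receives a CI
#' of the form estimate +/- 1.96 * sqrt(f_g), so that any two groups can be
#' compared by summing their floated variances.
#'
#' @param contrasts K-1 log-ORs versus the reference group.
#' @param floated a \code{\link{float_variances}} result for the same fit.
#' @return data.frame: group, log_or, or, ci_low, ci_high, floated_variance.
#' @export
floated_group_intervals <- function(contrasts, floated) {
  est <- c(0, unname(contrasts))
  se <- sqrt(floated$f)
  data.frame(group = seq_along(est), log_or = est, or = exp(est),
             ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
             floated_variance = floated$f, row.names = NULL)
}

#' Dose-response table across fifths of a marker
#'
#' Convenience wrapper: control-based fifths, adjusted grouped logistic fit,
#' floated variances and per-fifth ORs with floated CIs, plus the geometric
#' mean of the original-scale marker in each fifth.
#'
#' @param data case-control table.
#' @param marker log-scale marker column name.
#' @param covariates adjustment covariates.
#' @param n_groups number of groups (default fifths).
#' @return data.frame: marker, fifth, geometric_mean, or, ci_low, ci_high,
#'   n_cases, n_controls, floated_variance.
#' @export
quantile_or_table <- function(data, marker,
                              covariates = adjustment_tiers()$plus_lipid,
                              n_groups = 5) {
  cols <- unique(c(marker, covariates, "is_case"))
  data <- data[complete.cases(data[, intersect(cols, names(data))]), ,
               drop = FALSE]
  grouping <- quantile_grouping(data[[marker]],
                                data[[marker]][data$is_case == 0],
                                n_groups = n_groups)
  gfit <- fit_quantile_group_model(data, grouping, covariates)
  fl <- float_variances(gfit$cov)
  iv <- floated_group_intervals(gfit$contrasts, fl)
  data.frame(marker = marker, fifth = iv$group,
             geometric_mean = grouping$geometric_mean,
             or = iv$or, ci_low = iv$ci_low, ci_high = iv$ci_high,
             n_cases = gfit$n_cases, n_controls = gfit$n_controls,
             floated_variance = iv$floated_variance,
             row.names = NULL, stringsAsFactors = FALSE)
}
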