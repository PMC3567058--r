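#' Standardize a log-transformed exposure to unit SD
#'
#' Centres and scales a vector of already log-transformed values using the
#' mean and SD of a reference vector (by default the values themselves), so
#' that a regression coefficient on the result is interpretable per 1 SD
#' higher log level.  A difference of \code{sd_used} log units maps to
#' exactly one standardized unit; on the original scale 1 SD corresponds to
#' an \code{exp(sd_used)}-fold difference.
#'
#' @param values numeric vector on the natural-log scale.
#' @param sd_source reference vector whose mean/SD define the scale
#'   (e.g. the pooled case+control baseline values, or controls only).
#' @return list with \code{z} (standardized values) and \code{sd_used}.
#' @export
standardize_log_exposure <- function(values, sd_source = values) {
  sd_source <- sd_source[!is.na(sd_source)]
  if (length(unique(sd_source)) < 2) stop("sd_source has zero variance")
  s <- sd(sd_source)
  list(z = (values - mean(sd_source)) / s, sd_used = s)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximizes the binomial log-likelihood by Newton scoring (IRLS), declaring
#' convergence when the largest coefficient change falls below \code{tol} or
#' after \code{max_iter} iterations.  The covariance matrix is the inverse
#' observed information at the final estimate.  Perfect separation
#' (divergence of coefficients or fitted probabilities) and rank-deficient
#' designs raise explicit errors.
#'
#' @param design numeric model matrix, including the intercept column.
#' @param outcome binary 0/1 vector.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param max_iter iteration cap.
#' @return object of class \code{logistic_fit}: list with \code{coef},
#'   \code{vcov}, \code{loglik}, \code{n_obs}, \code{converged},
#'   \code{n_iterations}, and \code{loglik_trace}.
#' @export
fit_logistic_irls <- function(design, outcome, tol = 1e-8, max_iter = 50L) {
  design <- as.matrix(design)
  outcome <- as.numeric(outcome)
  if (nrow(design) != length(outcome)) stop("design/outcome length mismatch")
  if (anyNA(design) || anyNA(outcome)) stop("missing values in design or outcome")
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(outcome)) < 2) stop("outcome is constant")
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("design matrix is rank deficient (aliased: ",
         paste(bad, collapse = ", "), ")")
  }

  p <- ncol(design)
  beta <- numeric(p)
  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12) && max(abs(beta)) > 15)
      stop("apparent perfect separation: coefficients diverging")
    # weighted least squares step via QR of sqrt(w)-scaled design
    z <- eta + (outcome - mu) / w
    fit <- qr.solve(design * sqrt(w), sqrt(w) * z)
    delta <- fit - beta
    beta <- fit
    loglik_trace <- c(loglik_trace,
                      sum(outcome * log(plogis(drop(design %*% beta))) +
                          (1 - outcome) *
                            log(1 - plogis(drop(design %*% beta)))))
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    if (max(abs(beta)) > 15)
      stop("apparent perfect separation: coefficients diverging")
    eta_chk <- drop(design %*% beta)
    if (min(eta_chk[outcome == 1]) > max(eta_chk[outcome == 0]))
      stop("apparent perfect separation: linear predictor fully ",
           "discriminates cases from controls")
  }
  eta <- drop(design %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(design * sqrt(w))
  V <- solve(info)
  dimnames(V) <- list(colnames(design), colnames(design))
  names(beta) <- colnames(design)
  structure(list(coef = beta, vcov = V,
                 loglik = sum(outcome * log(mu) + (1 - outcome) * log(1 - mu)),
                 n_obs = nrow(design), converged = converged,
                 n_iterations = iter, loglik_trace = loglik_trace),
            class = "logistic_fit")
}
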