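#' Estimate a regression dilution ratio from serial measurements
#'
#' Regresses the repeat measurement on the baseline measurement plus
#' adjustment covariates; the baseline coefficient is the regression
#' dilution ratio (RDR), the attenuation factor linking associations of
#' single measurements to associations of long-term usual levels under the
#' classical error model.
#'
#' @param pairs data.frame with columns \code{baseline}, \code{repeat_meas}
#'   and any adjustment covariates; rows with missing values are dropped.
#' @param adjust covariate column names (default age- and sex-adjusted).
#' @return object of class \code{rdr_estimate}: list with \code{rdr},
#'   \code{se}, \code{ci_low}, \code{ci_high}, \code{n_pairs},
#'   \code{adjust}, and the calibration \code{model} used for usual-level
#'   prediction.
#' @export
estimate_rdr <- function(pairs, adjust = c("age", "sex")) {
  cols <- unique(c("baseline", "repeat_meas", adjust))
  d <- pairs[complete.cases(pairs[, intersect(cols, names(pairs))]), ,
             drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 complete serial pairs")
  if (var(d$baseline) == 0) stop("baseline values have zero variance")
  A <- covariate_design(d, adjust)
  df <- data.frame(y = d$repeat_meas, baseline = d$baseline)
  if (ncol(A) > 0) df <- cbind(df, as.data.frame(A))
  fit <- lm(y ~ ., data = df)
  b <- coef(fit)["baseline"]
  # a noiseless repeat (rdr exactly 1) is a legitimate perfect fit
  se <- suppressWarnings(sqrt(diag(vcov(fit)))["baseline"])
  structure(list(rdr = unname(b), se = unname(se),
                 ci_low = unname(b - 1.96 * se),
                 ci_high = unname(b + 1.96 * se),
                 n_pairs = nrow(d), adjust = adjust, model = fit),
            class = "rdr_estimate")
}

#' Predict usual (long-term average) levels from baseline measurements
#'
#' Applies the calibration regression underlying an RDR estimate to every
#' participant (not only the repeat subsample): predictions shrink each
#' baseline value toward the covariate-conditional mean with slope equal to
#' the RDR.
#'
#' @param rdr_model an \code{\link{estimate_rdr}} result.
#' @param newdata data.frame with a \code{baseline} column and the
#'   calibration covariates.
#' @return numeric vector of predicted usual levels.
#' @export
predict_usual_levels <- function(rdr_model, newdata) {
  need <- c("baseline", rdr_model$adjust)
  missing_cols <- setdiff(need, names(newdata))
  if (length(missing_cols) > 0)
    stop("newdata lacks calibration covariates: ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(newdata[, need]))
    stop("missing covariate or baseline values in newdata")
  A <- covariate_design(newdata, rdr_model$adjust)
  df <- data.frame(baseline = newdata$baseline)
  if (ncol(A) > 0) df <- cbind(df, as.data.frame(A))
  unname(stats::predict(rdr_model$model, newdata = df))
}

# single corrected fit: calibration on the repeat subsample, prediction for
# everyone, logistic fit of case status on standardized usual levels
corrected_fit_once <- function(data, marker, covariates, rdr_adjust,
                               sd_source) {
  base_col <- paste0(marker, "_log_base")
  rep_col <- paste0(marker, "_log_rep")
  pairs <- data.frame(baseline = data[[base_col]],
                      repeat_meas = data[[rep_col]],
                      data[, intersect(rdr_adjust, names(data)),
                           drop = FALSE])
  rdr <- estimate_rdr(pairs[!is.na(pairs$repeat_meas), , drop = FALSE],
                      adjust = rdr_adjust)
  usual <- predict_usual_levels(
    rdr, data.frame(baseline = data[[base_col]],
                    data[, intersect(rdr_adjust, names(data)),
                         drop = FALSE]))
  ref <- if (sd_source == "controls") data[[base_col]][data$is_case == 0]
         else data[[base_col]]
  # "per 1 SD" keeps referring to the baseline distribution
  sd_used <- sd(ref)
  z <- (usual - mean(ref)) / sd_used
  X <- cbind(`(Intercept)` = 1, marker_z = z,
             covariate_design(data, covariates))
  fit <- fit_logistic_irls(X, data$is_case)
  list(beta = unname(fit$coef["marker_z"]),
       se = sqrt(fit$vcov["marker_z", "marker_z"]),
       sd_used = sd_used, rdr = rdr)
}

#' Odds ratio per 1 SD corrected for within-person variability
#'
#' Two-stage correction: a calibration regression of repeat on baseline
#' measurements (the RDR model) predicts usual levels for every participant;
#' the logistic outcome model is then refit with usual levels in place of
#' baseline levels, standardized by the baseline SD so "per 1 SD" keeps its
#' original meaning.  The naive CI reuses the Wald SE of the second-stage
#' fit; the bootstrap CI resamples participants and repeats both stages,
#' propagating calibration uncertainty.
#'
#' @param data case-control table including repeat-measurement columns.
#' @param marker marker stem (\code{"tpa"}, \code{"ddimer"} or \code{"vwf"});
#'   columns \code{<marker>_log_base} / \code{<marker>_log_rep} are used.
#' @param covariates outcome-model adjustment covariates.
#' @param rdr_adjust calibration-model covariates (default age and sex).
#' @param ci_method \code{"bootstrap"} (default) or \code{"naive"}.
#' @param n_boot bootstrap replicates (percentile CI).
#' @param sd_source standardization sample for the baseline SD.
#' @param seed seed for bootstrap resampling.
#' @return data.frame row: marker, or, ci_low, ci_high, sd_used, rdr,
#'   ci_method, n.
#' @export
corrected_or_per_sd <- function(data, marker,
                                covariates = adjustment_tiers()$plus_lipid,
                                rdr_adjust = c("age", "sex"),
                                ci_method = c("bootstrap", "naive"),
                                n_boot = 500L, sd_source = c("pooled",
                                                             "controls"),
                                seed = 1L) {
  ci_method <- match.arg(ci_method)
  sd_source <- match.arg(sd_source)
  base_col <- paste0(marker, "_log_base")
  cols <- unique(c(base_col, covariates, rdr_adjust, "is_case"))
  data <- data[complete.cases(data[, intersect(cols, names(data))]), ,
               drop = FALSE]
  point <- corrected_fit_once(data, marker, covariates, rdr_adjust,
                              sd_source)
  if (ci_method == "naive") {
    lo <- point$beta - 1.96 * point$se
    hi <- point$beta + 1.96 * point$se
  } else {
    boots <- with_substream(seed, paste0("boot-", marker), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(data), replace = TRUE)
        tryCatch(corrected_fit_once(data[idx, , drop = FALSE], marker,
                                    covariates, rdr_adjust, sd_source)$beta,
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    boots <- boots[!is.na(boots)]
    if (length(boots) < n_boot / 2)
      stop("too many failed bootstrap replicates")
    qs <- quantile(boots, c(0.025, 0.975), type = 7)
    lo <- qs[1]; hi <- qs[2]
  }
  data.frame(marker = marker, or = exp(point$beta),
             ci_low = exp(unname(lo)), ci_high = exp(unname(hi)),
             sd_used = point$sd_used, rdr = point$rdr$rdr,
             ci_method = ci_method, n = nrow(data),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trend of within-person stability estimates with time between measurements
#'
#' Inverse-variance-weighted linear regression of study-specific stability
#' estimates (self-correlations or RDRs) on the gap in years between
#' measurements, with a two-sided z-test for the slope.
#'
#' @param estimates data.frame with columns \code{estimate}, \code{se},
#'   \code{gap_years}.
#' @return list with \code{slope}, \code{se}, \code{p}, \code{intercept}.
#' @export
rdr_time_trend <- function(estimates) {
  if (nrow(estimates) < 3) stop("need at least 3 estimates")
  if (length(unique(estimates$gap_years)) < 2) stop("all gaps are equal")
  w <- 1 / estimates$se^2
  fit <- lm(estimate ~ gap_years, data = estimates, weights = w)
  b <- coef(fit)["gap_years"]
  se <- sqrt(diag(vcov(fit)))["gap_years"]
  list(slope = unname(b), se = unname(se),
       p = unname(2 * pt(-abs(b / se), df = nrow(estimates) - 2)),
       intercept = unname(coef(fit)[1]))
}
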