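#' Progressive adjustment tiers
#'
#' Nested covariate sets used for progressively adjusted odds ratios:
#' \describe{
#'   \item{minimal}{age, sex, period of recruitment}
#'   \item{plus_nonlipid}{+ smoking, body mass index, history of diabetes,
#'     systolic blood pressure}
#'   \item{plus_lipid}{+ total cholesterol, log triglycerides}
#'   \item{plus_crp}{+ C-reactive protein (requires a \code{crp} column)}
#' }
#'
#' @param upto last tier to include.
#' @return named list of character covariate vectors, nested supersets.
#' @export
adjustment_tiers <- function(upto = c("plus_lipid", "plus_crp", "minimal",
                                      "plus_nonlipid")) {
  upto <- match.arg(upto)
  tiers <- list(
    minimal = c("age", "sex", "period"),
    plus_nonlipid = c("age", "sex", "period", "smoking", "bmi", "diabetes",
                      "sbp"),
    plus_lipid = c("age", "sex", "period", "smoking", "bmi", "diabetes",
                   "sbp", "tchol", "log_tg"),
    plus_crp = c("age", "sex", "period", "smoking", "bmi", "diabetes",
                 "sbp", "tchol", "log_tg", "crp"))
  tiers[seq_len(match(upto, names(tiers)))]
}

# expand covariates into a numeric design block: sex -> male indicator,
# period -> stage indicators (first stage reference), others as-is
covariate_design <- function(data, covariates) {
  if (length(covariates) == 0)
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  blocks <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("missing covariate column: ", v)
    if (v == "sex") {
      m <- cbind(as.numeric(x == "male"))
      colnames(m) <- "male"
      m
    } else if (v == "period") {
      f <- factor(x)
      if (nlevels(f) < 2) return(matrix(numeric(0), nrow(data), 0))
      m <- model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0("period", levels(f)[-1])
      m
    } else if (is.factor(x) || is.character(x)) {
      f <- factor(x)
      m <- model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0(v, levels(f)[-1])
      m
    } else {
      m <- cbind(as.numeric(x))
      colnames(m) <- v
      m
    }
  })
  do.call(cbind, blocks)
}

#' Per-1-SD odds ratios with progressive covariate adjustment
#'
#' Standardizes a log-scale marker column and fits an unconditional logistic
#' regression of case status on the standardized marker plus each tier's
#' covariates.  Rows are restricted to complete cases for the widest tier
#' requested so that n is constant across tiers.
#'
#' @param data case-control table with an \code{is_case} column.
#' @param marker name of the log-scale marker column
#'   (e.g. \code{"tpa_log_base"}).
#' @param tiers named list of covariate vectors, as from
#'   \code{\link{adjustment_tiers}}; must be nested in order.
#' @param sd_source \code{"pooled"} (cases + controls, default) or
#'   \code{"controls"}: which sample defines the standardizing SD.
#' @return data.frame, one row per tier: marker, tier, or, ci_low, ci_high,
#'   sd_used, n_cases, n_controls.
#' @export
or_per_sd_progressive <- function(data, marker,
                                  tiers = adjustment_tiers(),
                                  sd_source = c("pooled", "controls")) {
  sd_source <- match.arg(sd_source)
  widest <- tiers[[length(tiers)]]
  cols <- unique(c(marker, widest, "is_case"))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  data <- data[complete.cases(data[, cols]), , drop = FALSE]
  ref <- if (sd_source == "controls") {
    data[[marker]][data$is_case == 0]
  } else data[[marker]]
  std <- standardize_log_exposure(data[[marker]], ref)
  out <- lapply(names(tiers), function(tn) {
    X <- cbind(`(Intercept)` = 1, marker_z = std$z,
               covariate_design(data, tiers[[tn]]))
    fit <- fit_logistic_irls(X, data$is_case)
    b <- fit$coef["marker_z"]
    se <- sqrt(fit$vcov["marker_z", "marker_z"])
    data.frame(marker = marker, tier = tn, or = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               sd_used = std$sd_used,
               n_cases = sum(data$is_case == 1),
               n_controls = sum(data$is_case == 0),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Likelihood-ratio test for effect modification
#'
#' Compares logistic models with and without marker-by-modifier interaction
#' terms.  Continuous modifiers should be categorized beforehand (e.g. by
#' tertile cut-offs in controls, see \code{\link{tertile_groups}}).
#'
#' @param data case-control table.
#' @param marker log-scale marker column name.
#' @param modifier name of a categorical (or binary) modifier column.
#' @param covariates adjustment covariates of the base model.
#' @param sd_source standardization sample, as in
#'   \code{\link{or_per_sd_progressive}}.
#' @return list with \code{lrt_statistic}, \code{df}, \code{p_value}.
#' @export
interaction_lrt <- function(data, marker, modifier,
                            covariates = adjustment_tiers()$plus_lipid,
                            sd_source = c("pooled", "controls")) {
  sd_source <- match.arg(sd_source)
  cols <- unique(c(marker, modifier, covariates, "is_case"))
  data <- data[complete.cases(data[, intersect(cols, names(data))]), ,
               drop = FALSE]
  mod <- factor(data[[modifier]])
  if (nlevels(mod) < 2) stop("modifier is constant")
  ref <- if (sd_source == "controls") data[[marker]][data$is_case == 0]
         else data[[marker]]
  z <- standardize_log_exposure(data[[marker]], ref)$z
  mod_mat <- model.matrix(~ mod)[, -1, drop = FALSE]
  colnames(mod_mat) <- paste0("mod", seq_len(ncol(mod_mat)))
  Xbase <- cbind(`(Intercept)` = 1, marker_z = z, mod_mat,
                 covariate_design(data, setdiff(covariates, modifier)))
  inter <- z * mod_mat
  colnames(inter) <- paste0("marker_z:", colnames(mod_mat))
  reduced <- fit_logistic_irls(Xbase, data$is_case)
  full <- fit_logistic_irls(cbind(Xbase, inter), data$is_case)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- ncol(inter)
  list(lrt_statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Tertile grouping by control cut-offs
#'
#' @param values numeric vector for all subjects.
#' @param control_values values among controls defining the cut-offs.
#' @return integer group 1-3 (ties to the lower group).
#' @export
tertile_groups <- function(values, control_values = values) {
  cuts <- quantile(control_values, c(1, 2) / 3, na.rm = TRUE, type = 7)
  1L + rowSums(outer(values, cuts, ">"))
}

#' Adjusted percentage difference in a marker per covariate contrast
#'
#' Linear regression of the log marker on a covariate plus adjusters, among
#' controls.  For a continuous covariate the difference is expressed per 1 SD
#' higher covariate level, \code{100 * (exp(b * sd_cov) - 1)}; for a binary
#' covariate, relative to the reference category, \code{100 * (exp(b) - 1)}.
#' The 95\% CI is transformed the same way from the coefficient's Wald CI.
#'
#' @param controls control-only table.
#' @param marker log-scale marker column name.
#' @param covariate covariate column name.
#' @param adjust adjustment covariates (must not include \code{covariate}).
#' @return list with \code{pct}, \code{ci_low}, \code{ci_high},
#'   \code{per} ("sd" or "category") and \code{n}.
#' @export
percentage_difference <- function(controls, marker, covariate,
                                  adjust = c("age", "sex", "period")) {
  if (covariate %in% adjust)
    stop("covariate must not appear in the adjustment list")
  cols <- unique(c(marker, covariate, adjust))
  d <- controls[complete.cases(controls[, cols]), , drop = FALSE]
  x <- d[[covariate]]
  if (covariate == "sex") x <- as.numeric(x == "male")
  binary <- all(x %in% c(0, 1))
  X <- data.frame(y = d[[marker]], x = as.numeric(x))
  A <- covariate_design(d, adjust)
  fit <- lm(y ~ ., data = cbind(X, as.data.frame(A)))
  b <- coef(fit)["x"]
  se <- sqrt(diag(vcov(fit)))["x"]
  mult <- if (binary) 1 else sd(x)
  est <- unname(c(b, b - 1.96 * se, b + 1.96 * se)) * mult
  list(pct = 100 * (exp(est[1]) - 1), ci_low = 100 * (exp(est[2]) - 1),
       ci_high = 100 * (exp(est[3]) - 1),
       per = if (binary) "category" else "sd", n = nrow(d))
}
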