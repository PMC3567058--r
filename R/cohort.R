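#' @importFrom stats rnorm runif rbinom plogis qlogis quantile sd var cov cor
#'   lm glm coef vcov pchisq pnorm qnorm pt dnorm integrate complete.cases
#'   model.matrix binomial setNames
NULL

MARKERS <- c("tpa", "ddimer", "vwf")
COVARIATES <- c("age", "male", "smoking", "diabetes", "bmi", "sbp", "tchol",
                "log_tg")

PARTICIPANT_CSV_HEADER <- c(
  "id", "age", "sex", "period", "smoking", "diabetes", "bmi", "sbp", "tchol",
  "log_tg", "tpa_log_base", "ddimer_log_base", "vwf_log_base",
  "tpa_log_rep", "ddimer_log_rep", "vwf_log_rep", "is_case")

# Cross-sectional associations of covariates with usual log-marker levels
# (log units per covariate unit).  Calibrated to reported percentage
# differences per 1 SD in controls, halved because the generator draws
# covariates independently whereas the reported marginal associations arise
# from intercorrelated risk factors.
default_marker_covariate_assoc <- function() {
  m <- rbind(
    tpa    = c(age = 0.0045, male =  0.104, smoking = 0.020, diabetes = 0,
               bmi =  0.0247, sbp =  0.0026, tchol =  0.031, log_tg =  0.238),
    ddimer = c(age = 0.0124, male = -0.164, smoking = 0.034, diabetes = 0,
               bmi = -0.0236, sbp = -0.0016, tchol = -0.023, log_tg = -0.189),
    vwf    = c(age = 0.0050, male =  0.015, smoking = 0.024, diabetes = 0,
               bmi =  0.0014, sbp =  0.0003, tchol =  0.000, log_tg =  0.025))
  m
}

#' Specification of a synthetic prospective cohort
#'
#' Defines the joint distribution of a middle-aged population-based cohort
#' with three log-normally distributed hemostatic markers (t-PA antigen,
#' D-dimer, VWF), conventional cardiovascular risk factors, classical
#' within-person measurement error calibrated to target regression dilution
#' ratios, and a logistic event model for incident coronary heart disease.
#'
#' Marker scale conventions: \code{marker_log_means} and
#' \code{marker_log_sds} describe the marginal distribution of
#' single-occasion (baseline) log measurements, the quantity summarised in
#' participant-characteristics tables.  True usual (long-term average)
#' levels then have SD \code{marker_log_sds * sqrt(target_rdrs)} and the
#' classical error SD is \code{marker_log_sds * sqrt(1 - target_rdrs)}, so
#' that regressing a repeat measurement on baseline recovers the target RDR.
#' \code{marker_corr} is the correlation matrix of the true usual levels.
#' \code{true_log_or_per_sd} is expressed per 1 SD of the baseline
#' (single-measurement) distribution, the same scale on which analyses
#' report odds ratios, so a measurement-error-corrected analysis targets
#' \code{true_log_or_per_sd} and a naive analysis targets approximately
#' \code{target_rdrs * true_log_or_per_sd}.
#'
#' @param n_participants cohort size (>= 100).
#' @param n_periods number of recruitment stages.
#' @param age_range numeric length-2, uniform age range in years.
#' @param male_fraction proportion male.
#' @param covariate_params named list: smoking_prev, diabetes_prev, bmi_mean,
#'   bmi_sd, sbp_mean, sbp_sd, tchol_mean, tchol_sd, logtg_mean, logtg_sd.
#' @param marker_log_means length-3 means of baseline log levels
#'   (t-PA antigen, D-dimer, VWF).
#' @param marker_log_sds length-3 SDs of baseline log levels.
#' @param marker_corr 3x3 correlation matrix of true usual log levels.
#' @param target_rdrs length-3 regression dilution ratios in (0, 1].
#' @param repeat_gap_years mean years between baseline and repeat measurement.
#' @param repeat_gap_sd SD of the gap.
#' @param repeat_subsample_n number of participants with a repeat measurement.
#' @param rdr_decay_per_year optional linear decay of the self-correlation of
#'   usual levels per year of gap (0 = stable usual levels).
#' @param true_log_or_per_sd length-3 true log odds ratios per 1 baseline SD.
#' @param covariate_log_ors named vector of log-ORs per covariate unit.
#' @param marker_covariate_assoc 3x8 matrix of covariate effects on usual
#'   log levels (log units per covariate unit); rows markers, columns
#'   covariates.
#' @param baseline_risk event probability at reference covariate values
#'   (all covariates and markers at their means).
#' @param seed master integer seed.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_participants = 18912,
                        n_periods = 5,
                        age_range = c(40, 70),
                        male_fraction = 0.483,
                        covariate_params = list(
                          smoking_prev = 0.48, diabetes_prev = 0.02,
                          bmi_mean = 25.4, bmi_sd = 3.7,
                          sbp_mean = 141.9, sbp_sd = 20.1,
                          tchol_mean = 6.4, tchol_sd = 1.1,
                          logtg_mean = 0.0, logtg_sd = 0.4),
                        marker_log_means = c(2.5, 4.8, 4.6),
                        marker_log_sds = c(0.5, 1.0, 0.4),
                        marker_corr = rbind(c(1, -0.15, 0.15),
                                            c(-0.15, 1, 0.10),
                                            c(0.15, 0.10, 1)),
                        target_rdrs = c(0.47, 0.30, 0.55),
                        repeat_gap_years = 11.6,
                        repeat_gap_sd = 1.3,
                        repeat_subsample_n = 371,
                        rdr_decay_per_year = 0,
                        true_log_or_per_sd = log(c(1.15, 1.11, 1.10)),
                        covariate_log_ors = c(
                          age = 0.08, male = 0.7, smoking = 0.6,
                          diabetes = 0.7, bmi = 0.04, sbp = 0.015,
                          tchol = 0.25, log_tg = 0.4),
                        marker_covariate_assoc = default_marker_covariate_assoc(),
                        baseline_risk = 0.09,
                        seed = 1L) {
  spec <- list(
    n_participants = as.integer(n_participants), n_periods = as.integer(n_periods),
    age_range = as.numeric(age_range), male_fraction = male_fraction,
    covariate_params = covariate_params,
    marker_log_means = as.numeric(marker_log_means),
    marker_log_sds = as.numeric(marker_log_sds),
    marker_corr = unname(as.matrix(marker_corr)),
    target_rdrs = as.numeric(target_rdrs),
    repeat_gap_years = repeat_gap_years, repeat_gap_sd = repeat_gap_sd,
    repeat_subsample_n = as.integer(repeat_subsample_n),
    rdr_decay_per_year = rdr_decay_per_year,
    true_log_or_per_sd = as.numeric(true_log_or_per_sd),
    covariate_log_ors = covariate_log_ors[COVARIATES],
    marker_covariate_assoc = as.matrix(marker_covariate_assoc)[, COVARIATES],
    baseline_risk = baseline_risk, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_participants < 100)
    stop("n_participants must be at least 100")
  if (any(spec$marker_log_sds <= 0))
    stop("marker_log_sds must be positive")
  if (any(spec$target_rdrs <= 0) || any(spec$target_rdrs > 1))
    stop("target_rdrs must lie in (0, 1]")
  R <- spec$marker_corr
  if (nrow(R) != 3 || ncol(R) != 3)
    stop("marker_corr must be 3x3")
  if (max(abs(R - t(R))) > 1e-8)
    stop("marker_corr must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("marker_corr must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("marker_corr is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  if (length(spec$age_range) != 2 || diff(spec$age_range) <= 0)
    stop("age_range must be (min, max) with min < max")
  if (any(is.na(spec$covariate_log_ors)))
    stop("covariate_log_ors must name all of: ",
         paste(COVARIATES, collapse = ", "))
  invisible(spec)
}

# theoretical means and variances of the generator's covariates, used to
# centre the event model and to decompose the usual-level covariance
covariate_moments <- function(spec) {
  p <- spec$covariate_params
  means <- c(age = mean(spec$age_range), male = spec$male_fraction,
             smoking = p$smoking_prev, diabetes = p$diabetes_prev,
             bmi = p$bmi_mean, sbp = p$sbp_mean, tchol = p$tchol_mean,
             log_tg = p$logtg_mean)
  vars <- c(age = diff(spec$age_range)^2 / 12,
            male = spec$male_fraction * (1 - spec$male_fraction),
            smoking = p$smoking_prev * (1 - p$smoking_prev),
            diabetes = p$diabetes_prev * (1 - p$diabetes_prev),
            bmi = p$bmi_sd^2, sbp = p$sbp_sd^2, tchol = p$tchol_sd^2,
            log_tg = p$logtg_sd^2)
  list(means = means, vars = vars)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates independently from the marginals in \code{spec}, true
#' usual log-marker levels from a trivariate normal whose marginal
#' covariance (covariate effects plus a Gaussian residual) matches
#' \code{marker_corr} and \code{marker_log_sds * sqrt(target_rdrs)} exactly,
#' baseline and repeat measurements under the classical additive error model
#' on the log scale, and incident-CHD status from a logistic model in
#' standardized usual levels and centred covariates.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return data.frame with one row per participant: the fixed CSV columns
#'   plus ground-truth columns \code{*_log_usual} and \code{rep_gap_years}.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_participants
  mom <- covariate_moments(spec)
  p <- spec$covariate_params

  with_substream(spec$seed, "cohort", {
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    male <- rbinom(n, 1, spec$male_fraction)
    period <- sample.int(spec$n_periods, n, replace = TRUE)
    smoking <- rbinom(n, 1, p$smoking_prev)
    diabetes <- rbinom(n, 1, p$diabetes_prev)
    bmi <- rnorm(n, p$bmi_mean, p$bmi_sd)
    sbp <- rnorm(n, p$sbp_mean, p$sbp_sd)
    tchol <- rnorm(n, p$tchol_mean, p$tchol_sd)
    log_tg <- rnorm(n, p$logtg_mean, p$logtg_sd)

    X <- cbind(age = age, male = male, smoking = smoking, diabetes = diabetes,
               bmi = bmi, sbp = sbp, tchol = tchol, log_tg = log_tg)
    Xc <- sweep(X, 2, mom$means[colnames(X)])

    sd_base <- spec$marker_log_sds
    sd_usual <- sd_base * sqrt(spec$target_rdrs)
    sigma_usual <- diag(sd_usual) %*% spec$marker_corr %*% diag(sd_usual)
    B <- spec$marker_covariate_assoc                       # 3 x 8
    sigma_cov <- B %*% diag(mom$vars[COVARIATES]) %*% t(B)
    sigma_resid <- sigma_usual - sigma_cov
    ev <- eigen(sigma_resid, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("covariate effects explain more usual-level (co)variance than ",
           "marker_corr/marker_log_sds allow; reduce marker_covariate_assoc")
    L <- chol(sigma_resid)
    usual <- sweep(Xc %*% t(B) + matrix(rnorm(n * 3), n, 3) %*% L,
                   2, spec$marker_log_means, "+")
    colnames(usual) <- MARKERS

    sd_err <- sd_base * sqrt(1 - spec$target_rdrs)
    baseline <- usual +
      matrix(rnorm(n * 3), n, 3) %*% diag(sd_err)

    # repeat subsample: usual level at the repeat visit may drift (optional
    # linear decay of the self-correlation with gap), plus fresh error
    rep_idx <- sort(sample.int(n, min(spec$repeat_subsample_n, n)))
    gap <- pmax(0.5, rnorm(length(rep_idx), spec$repeat_gap_years,
                           spec$repeat_gap_sd))
    rho <- pmin(1, pmax(0, 1 - spec$rdr_decay_per_year * gap))
    mu <- matrix(spec$marker_log_means, length(rep_idx), 3, byrow = TRUE)
    usual2 <- mu + rho * (usual[rep_idx, , drop = FALSE] - mu) +
      sqrt(1 - rho^2) *
        (matrix(rnorm(length(rep_idx) * 3), ncol = 3) %*% diag(sd_usual))
    repeat_meas <- usual2 +
      matrix(rnorm(length(rep_idx) * 3), ncol = 3) %*% diag(sd_err)
    if (all(sd_err == 0) && spec$rdr_decay_per_year == 0)
      repeat_meas <- usual[rep_idx, , drop = FALSE]

    # event model: logistic in usual levels standardized per 1 baseline SD
    z <- sweep(sweep(usual, 2, spec$marker_log_means), 2, sd_base, "/")
    lp <- qlogis(spec$baseline_risk) +
      drop(z %*% spec$true_log_or_per_sd) +
      drop(Xc %*% spec$covariate_log_ors[colnames(X)])
    is_case <- rbinom(n, 1, plogis(lp))

    out <- data.frame(
      id = seq_len(n), age = age, sex = ifelse(male == 1, "male", "female"),
      period = period, smoking = smoking, diabetes = diabetes, bmi = bmi,
      sbp = sbp, tchol = tchol, log_tg = log_tg,
      tpa_log_base = baseline[, 1], ddimer_log_base = baseline[, 2],
      vwf_log_base = baseline[, 3],
      tpa_log_rep = NA_real_, ddimer_log_rep = NA_real_,
      vwf_log_rep = NA_real_, is_case = is_case,
      tpa_log_usual = usual[, 1], ddimer_log_usual = usual[, 2],
      vwf_log_usual = usual[, 3], rep_gap_years = NA_real_,
      stringsAsFactors = FALSE)
    out$tpa_log_rep[rep_idx] <- repeat_meas[, 1]
    out$ddimer_log_rep[rep_idx] <- repeat_meas[, 2]
    out$vwf_log_rep[rep_idx] <- repeat_meas[, 3]
    out$rep_gap_years[rep_idx] <- gap
    out
  })
}

#' Draw a frequency-matched nested case-control sample
#'
#' Includes every case; within each stratum of the matching factors, draws
#' \code{round(ratio * cases)} controls without replacement from the
#' non-cases of that stratum, so the control distribution of the matching
#' factors mirrors the cases' without individual pairing.
#'
#' @param cohort data.frame from \code{\link{generate_cohort}} (or a
#'   compatible participant table).
#' @param ratio target controls per case (> 0).
#' @param matching character vector of matching variables; \code{"age_band"}
#'   means 5-year age bands derived from \code{age}.
#' @param seed integer seed for control sampling.
#' @return object of class \code{case_control_set}: list with
#'   \code{case_ids}, \code{control_ids}, \code{matching_factors},
#'   \code{ratio}.
#' @export
sample_nested_case_control <- function(cohort, ratio = 1.88,
                                       matching = c("sex", "age_band",
                                                    "period"),
                                       seed = 1L) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (ratio <= 0) stop("ratio must be positive")
  vars <- lapply(matching, function(v) {
    if (v == "age_band") 5 * floor(cohort$age / 5) else cohort[[v]]
  })
  stratum <- interaction(vars, drop = TRUE)
  case_ids <- cohort$id[cohort$is_case == 1]
  if (length(case_ids) == 0) stop("cohort contains no cases")
  thin <- character(0)
  control_ids <- with_substream(seed, "ncc-sampling", {
    unlist(lapply(levels(stratum), function(s) {
      in_s <- stratum == s
      n_cases_s <- sum(in_s & cohort$is_case == 1)
      if (n_cases_s == 0) return(integer(0))
      pool <- cohort$id[in_s & cohort$is_case == 0]
      want <- round(ratio * n_cases_s)
      if (length(pool) < want) {
        thin <<- c(thin, sprintf("%s (%d for %d)", s, length(pool), want))
        return(pool)
      }
      pool[sample.int(length(pool), want)]
    }), use.names = FALSE)
  })
  if (length(thin) > 0)
    warning(length(thin), " strata had fewer controls available than ",
            "requested; all their controls were taken: ",
            paste(thin, collapse = "; "))
  structure(list(case_ids = case_ids, control_ids = sort(control_ids),
                 matching_factors = matching, ratio = ratio),
            class = "case_control_set")
}

#' Extract the analysis table for a case-control set
#'
#' @param cohort participant table.
#' @param ccset a \code{case_control_set}.
#' @return rows of \code{cohort} for the selected cases and controls.
#' @export
case_control_data <- function(cohort, ccset) {
  cohort[cohort$id %in% c(ccset$case_ids, ccset$control_ids), , drop = FALSE]
}

#' Write / read a participant table as CSV
#'
#' Fixed 17-column header; missing repeat measurements are written as empty
#' fields.  Ground-truth columns are not persisted.
#'
#' @param cohort participant table.
#' @param path file path.
#' @export
write_participants_csv <- function(cohort, path) {
  utils::write.csv(cohort[, PARTICIPANT_CSV_HEADER], path,
                   row.names = FALSE, na = "")
}

#' @rdname write_participants_csv
#' @return \code{read_participants_csv}: participant data.frame.
#' @export
read_participants_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PARTICIPANT_CSV_HEADER, names(d))
  if (length(missing_cols) > 0)
    stop("participant CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  d
}

#' Serialize a cohort specification to YAML (lossless round trip)
#'
#' @param spec a \code{cohort_spec}.
#' @param path file path.
#' @export
write_cohort_spec <- function(spec, path) {
  s <- unclass(spec)
  s$marker_corr <- lapply(seq_len(nrow(s$marker_corr)),
                          function(i) as.numeric(s$marker_corr[i, ]))
  s$marker_covariate_assoc <- lapply(
    seq_len(nrow(s$marker_covariate_assoc)),
    function(i) as.numeric(s$marker_covariate_assoc[i, ]))
  s$covariate_log_ors <- as.list(s$covariate_log_ors)
  yaml::write_yaml(s, path, precision = 15)
}

#' @rdname write_cohort_spec
#' @return \code{read_cohort_spec}: the restored \code{cohort_spec}.
#' @export
read_cohort_spec <- function(path) {
  s <- yaml::read_yaml(path)
  corr <- do.call(rbind, s$marker_corr)
  assoc <- do.call(rbind, s$marker_covariate_assoc)
  dimnames(assoc) <- list(MARKERS, COVARIATES)
  cohort_spec(
    n_participants = s$n_participants, n_periods = s$n_periods,
    age_range = unlist(s$age_range), male_fraction = s$male_fraction,
    covariate_params = s$covariate_params,
    marker_log_means = unlist(s$marker_log_means),
    marker_log_sds = unlist(s$marker_log_sds),
    marker_corr = corr, target_rdrs = unlist(s$target_rdrs),
    repeat_gap_years = s$repeat_gap_years, repeat_gap_sd = s$repeat_gap_sd,
    repeat_subsample_n = s$repeat_subsample_n,
    rdr_decay_per_year = s$rdr_decay_per_year,
    true_log_or_per_sd = unlist(s$true_log_or_per_sd),
    covariate_log_ors = unlist(s$covariate_log_ors),
    marker_covariate_assoc = assoc,
    baseline_risk = s$baseline_risk, seed = s$seed)
}
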