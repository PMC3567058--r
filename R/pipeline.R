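marker_base_cols <- function() paste0(MARKERS, "_log_base")

# small stable hash of a configuration list for the run manifest
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", h)
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
}

write_output <- function(d, out_dir, name, files, log_path) {
  path <- file.path(out_dir, name)
  utils::write.csv(d, path, row.names = FALSE)
  log_line(log_path, "wrote ", name, " (", nrow(d), " rows)")
  files[[name]] <- nrow(d)
  files
}

finish_manifest <- function(out_dir, mode, seed, config, files, counts) {
  manifest <- list(mode = mode, seed = seed,
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("hemocc")),
                   r_version = as.character(getRversion()),
                   filtering_counts = counts,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full case-control analysis pipeline
#'
#' Generates (or loads) a participant table, draws a frequency-matched
#' nested case-control sample, and writes CSV outputs for every analysis
#' stage: adjusted percentage differences among controls, per-1-SD odds
#' ratios with progressive adjustment, odds ratios across fifths with
#' floated CIs, interaction tests, regression dilution ratios, and
#' corrected odds ratios.  A JSON manifest (seed, config hash, file row
#' counts, complete-case filtering counts) makes the run reproducible.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a \code{\link{cohort_spec}}; ignored when \code{input} given.
#' @param input optional participant CSV to analyse instead of simulating.
#' @param seed master seed (overrides \code{spec$seed} when simulating).
#' @param ratio controls per case for the nested sample.
#' @param sd_source standardization sample, \code{"pooled"} or
#'   \code{"controls"}.
#' @param ci_method CI construction for corrected ORs.
#' @param n_boot bootstrap replicates when \code{ci_method = "bootstrap"}.
#' @return the manifest, invisibly.
#' @export
run_casecontrol_analysis <- function(out_dir, spec = cohort_spec(),
                                     input = NULL, seed = spec$seed,
                                     ratio = 1.88,
                                     sd_source = "pooled",
                                     ci_method = "bootstrap",
                                     n_boot = 500L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  files <- list()
  counts <- list()
  config <- list(spec = if (is.null(input)) unclass(spec) else input,
                 ratio = ratio, sd_source = sd_source,
                 ci_method = ci_method, n_boot = n_boot, seed = seed)

  if (is.null(input)) {
    spec$seed <- as.integer(seed)
    cohort <- generate_cohort(spec)
    log_line(log_path, "simulated cohort: n = ", nrow(cohort),
             ", cases = ", sum(cohort$is_case))
  } else {
    cohort <- read_participants_csv(input)
    log_line(log_path, "loaded cohort from ", input, ": n = ", nrow(cohort))
  }
  counts$cohort_n <- nrow(cohort)
  counts$cohort_cases <- sum(cohort$is_case)

  ccset <- sample_nested_case_control(cohort, ratio = ratio,
                                      seed = seed)
  cc <- case_control_data(cohort, ccset)
  log_line(log_path, "nested case-control sample: ",
           length(ccset$case_ids), " cases, ",
           length(ccset$control_ids), " controls")
  counts$cc_cases <- length(ccset$case_ids)
  counts$cc_controls <- length(ccset$control_ids)

  tiers <- adjustment_tiers("plus_lipid")
  cc_complete <- cc[complete.cases(cc[, c(marker_base_cols(),
                                          tiers$plus_lipid, "is_case")]), ]
  counts$cc_complete <- nrow(cc_complete)
  log_line(log_path, "complete cases at widest tier: ", nrow(cc_complete))

  # Table-1-style adjusted percentage differences among controls
  controls <- cc_complete[cc_complete$is_case == 0, ]
  pd_rows <- list()
  for (cov in c("age", "sex", "smoking", "bmi", "sbp", "tchol", "log_tg")) {
    for (m in seq_along(MARKERS)) {
      pd <- percentage_difference(
        controls, marker_base_cols()[m], cov,
        adjust = setdiff(c("age", "sex", "period"), cov))
      pd_rows[[length(pd_rows) + 1]] <- data.frame(
        covariate = cov, marker = MARKERS[m], pct = pd$pct,
        ci_low = pd$ci_low, ci_high = pd$ci_high, per = pd$per)
    }
  }
  files <- write_output(do.call(rbind, pd_rows), out_dir,
                        "table1_percentage_differences.csv", files, log_path)

  # Table-2-style progressive per-SD ORs
  or_rows <- lapply(marker_base_cols(), function(mc)
    or_per_sd_progressive(cc_complete, mc, tiers, sd_source = sd_source))
  files <- write_output(do.call(rbind, or_rows), out_dir,
                        "table2_or_per_sd.csv", files, log_path)

  # Fig-2-style fifths with floated CIs
  q_rows <- lapply(marker_base_cols(), function(mc)
    quantile_or_table(cc_complete, mc, tiers$plus_lipid))
  files <- write_output(do.call(rbind, q_rows), out_dir,
                        "fig2_fifths_floated.csv", files, log_path)

  # interaction tests: marker x modifier
  cc_complete$bmi_tertile <- tertile_groups(
    cc_complete$bmi, cc_complete$bmi[cc_complete$is_case == 0])
  int_rows <- list()
  for (mod in c("sex", "smoking", "diabetes", "bmi_tertile")) {
    for (m in seq_along(MARKERS)) {
      lrt <- interaction_lrt(cc_complete, marker_base_cols()[m], mod,
                             covariates = tiers$plus_lipid,
                             sd_source = sd_source)
      int_rows[[length(int_rows) + 1]] <- data.frame(
        marker = MARKERS[m], modifier = mod, lrt = lrt$lrt_statistic,
        df = lrt$df, p = lrt$p_value)
    }
  }
  files <- write_output(do.call(rbind, int_rows), out_dir,
                        "interaction_tests.csv", files, log_path)

  # RDR estimates from the repeat subsample (cohort-wide), Table-S3 style
  rdr_rows <- list()
  for (m in seq_along(MARKERS)) {
    rep_col <- paste0(MARKERS[m], "_log_rep")
    pairs <- data.frame(baseline = cohort[[marker_base_cols()[m]]],
                        repeat_meas = cohort[[rep_col]],
                        age = cohort$age, sex = cohort$sex,
                        gap = cohort$rep_gap_years %||% NA_real_)
    pairs <- pairs[!is.na(pairs$repeat_meas), ]
    est <- estimate_rdr(pairs)
    rdr_rows[[m]] <- data.frame(
      variable = MARKERS[m], rdr = est$rdr, se = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high, n_pairs = est$n_pairs,
      mean_gap_years = mean(pairs$gap, na.rm = TRUE))
  }
  files <- write_output(do.call(rbind, rdr_rows), out_dir,
                        "rdr_estimates.csv", files, log_path)
  counts$repeat_pairs <- rdr_rows[[1]]$n_pairs

  # corrected ORs at the widest tier
  corr_rows <- lapply(MARKERS, function(m)
    corrected_or_per_sd(cc_complete, m, covariates = tiers$plus_lipid,
                        ci_method = ci_method, n_boot = n_boot,
                        sd_source = sd_source, seed = seed))
  files <- write_output(do.call(rbind, corr_rows), out_dir,
                        "corrected_or_per_sd.csv", files, log_path)

  finish_manifest(out_dir, "casecontrol", seed, config, files, counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the meta-analysis pipeline
#'
#' Harmonizes published (or simulated) study estimates to the per-1-SD
#' scale and writes, per marker: forest data with the random-effects
#' summary, funnel data with pseudo-CI bounds, meta-regression across
#' study-level covariates, Egger's test, and the >= 500-case subgroup
#' comparison.  Markers with fewer than 2 studies are skipped with a
#' warning.
#'
#' @param out_dir output directory.
#' @param estimates estimate data.frame (e.g. from
#'   \code{\link{generate_study_estimates}} or
#'   \code{\link{read_estimates_csv}}).
#' @param seed seed recorded in the manifest.
#' @param subgroup_cases case-count threshold for the size subgroup
#'   comparison.
#' @return the manifest, invisibly.
#' @export
run_meta_analysis <- function(out_dir, estimates, seed = 1L,
                              subgroup_cases = 500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  files <- list()
  counts <- list(input_estimates = nrow(estimates))
  config <- list(seed = seed, subgroup_cases = subgroup_cases,
                 n_estimates = nrow(estimates))

  forest <- list(); funnel <- list(); metareg <- list()
  egger <- list(); subgroups <- list()
  for (m in unique(estimates$marker)) {
    est_m <- estimates[estimates$marker == m, , drop = FALSE]
    if (nrow(est_m) < 2) {
      warning("marker ", m, " has fewer than 2 studies; skipped")
      log_line(log_path, "skipped marker ", m, " (", nrow(est_m), " study)")
      next
    }
    h <- harmonize_to_per_sd(est_m)
    pool <- pool_random_effects(h$log_rr_per_sd, h$se)
    log_line(log_path, "marker ", m, ": k = ", pool$k,
             ", pooled RR = ", round(exp(pool$pooled), 3),
             ", I2 = ", round(pool$i2, 1), "%")

    forest[[m]] <- rbind(
      data.frame(marker = m, study = h$study, rr = exp(h$log_rr_per_sd),
                 ci_low = exp(h$log_rr_per_sd - 1.96 * h$se),
                 ci_high = exp(h$log_rr_per_sd + 1.96 * h$se),
                 n_cases = est_m$n_cases,
                 adjustment_degree = est_m$adjustment_degree,
                 weight_pct = 100 / (h$se^2 + pool$tau2) /
                   sum(1 / (h$se^2 + pool$tau2)), is_summary = FALSE),
      data.frame(marker = m, study = "RE summary", rr = exp(pool$pooled),
                 ci_low = exp(pool$ci_low), ci_high = exp(pool$ci_high),
                 n_cases = sum(est_m$n_cases), adjustment_degree = NA,
                 weight_pct = 100, is_summary = TRUE))

    fe_pool <- sum(h$log_rr_per_sd / h$se^2) / sum(1 / h$se^2)
    funnel[[m]] <- data.frame(
      marker = m, study = h$study, log_rr = h$log_rr_per_sd, se = h$se,
      pseudo_low = fe_pool - 1.96 * h$se, pseudo_high = fe_pool + 1.96 * h$se)

    for (cov in c("adjustment_degree", "followup_y", "baseline_year",
                  "storage_c")) {
      mr <- tryCatch(meta_regress(h$log_rr_per_sd, h$se, est_m[[cov]]),
                     error = function(e) NULL)
      if (!is.null(mr))
        metareg[[paste(m, cov)]] <- data.frame(
          marker = m, covariate = cov, slope = mr$slope, se = mr$se,
          p = mr$p, tau2 = mr$tau2)
    }

    eg <- egger_test(h$log_rr_per_sd, h$se)
    egger[[m]] <- data.frame(marker = m, intercept = eg$intercept,
                             se = eg$se, t = eg$t, df = eg$df, p = eg$p)

    grp <- est_m$n_cases >= subgroup_cases
    sg <- tryCatch(subgroup_compare(h$log_rr_per_sd, h$se,
                                    ifelse(grp, "large", "small")),
                   error = function(e) NULL)
    if (!is.null(sg))
      subgroups[[m]] <- data.frame(
        marker = m,
        group = names(sg$groups),
        k = vapply(sg$groups, `[[`, numeric(1), "k"),
        rr = exp(vapply(sg$groups, `[[`, numeric(1), "pooled")),
        ci_low = exp(vapply(sg$groups, `[[`, numeric(1), "ci_low")),
        ci_high = exp(vapply(sg$groups, `[[`, numeric(1), "ci_high")),
        p_between = sg$p, row.names = NULL)
  }

  files <- write_output(do.call(rbind, forest), out_dir, "forest.csv",
                        files, log_path)
  files <- write_output(do.call(rbind, funnel), out_dir, "funnel.csv",
                        files, log_path)
  if (length(metareg) > 0)
    files <- write_output(do.call(rbind, metareg), out_dir,
                          "meta_regression.csv", files, log_path)
  files <- write_output(do.call(rbind, egger), out_dir, "egger.csv",
                        files, log_path)
  if (length(subgroups) > 0)
    files <- write_output(do.call(rbind, subgroups), out_dir,
                          "subgroup_size.csv", files, log_path)

  finish_manifest(out_dir, "meta", seed, config, files, counts)
}
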