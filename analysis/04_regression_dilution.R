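#!/usr/bin/env Rscript
# Regression dilution: estimate RDRs from the repeat-measurement subsample
# and correct the per-1-SD odds ratios to usual (long-term average) levels.

source(file.path("analysis", "00_common.R"))
seed <- parse_seed()

cohort <- load_cohort()
cc <- load_case_control(cohort, seed)
tiers <- adjustment_tiers("plus_lipid")
markers <- c("tpa", "ddimer", "vwf")
cc <- cc[complete.cases(cc[, c(paste0(markers, "_log_base"),
                               tiers$plus_lipid, "is_case")]), ]
out <- results_dir("dilution")

rdrs <- do.call(rbind, lapply(markers, function(m) {
  pairs <- data.frame(baseline = cohort[[paste0(m, "_log_base")]],
                      repeat_meas = cohort[[paste0(m, "_log_rep")]],
                      age = cohort$age, sex = cohort$sex)
  est <- estimate_rdr(pairs[!is.na(pairs$repeat_meas), ])
  data.frame(marker = m, rdr = est$rdr, se = est$se, ci_low = est$ci_low,
             ci_high = est$ci_high, n_pairs = est$n_pairs)
}))
save_table(rdrs, out, "rdr_estimates.csv")

corrected <- do.call(rbind, lapply(markers, function(m)
  corrected_or_per_sd(cc, m, covariates = tiers$plus_lipid,
                      ci_method = "bootstrap", n_boot = 500, seed = seed)))
save_table(corrected, out, "corrected_or_per_sd.csv")
print(corrected[, c("marker", "or", "ci_low", "ci_high", "rdr")], digits = 3)
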