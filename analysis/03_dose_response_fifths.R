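#!/usr/bin/env Rscript
# Dose-response across fifths of each marker (cut-offs from the control
# distribution) with floated confidence intervals, plus interaction tests
# for effect modification by sex, smoking, diabetes and BMI tertile.

source(file.path("analysis", "00_common.R"))
seed <- parse_seed()

cohort <- load_cohort()
cc <- load_case_control(cohort, seed)
tiers <- adjustment_tiers("plus_lipid")
markers <- paste0(c("tpa", "ddimer", "vwf"), "_log_base")
cc <- cc[complete.cases(cc[, c(markers, tiers$plus_lipid, "is_case")]), ]
out <- results_dir("case_control")

fifths <- do.call(rbind, lapply(markers, function(m)
  quantile_or_table(cc, m, tiers$plus_lipid)))
save_table(fifths, out, "fig2_fifths_floated.csv")

cc$bmi_tertile <- tertile_groups(cc$bmi, cc$bmi[cc$is_case == 0])
ints <- do.call(rbind, lapply(
  c("sex", "smoking", "diabetes", "bmi_tertile"),
  function(mod) do.call(rbind, lapply(markers, function(m) {
    lrt <- interaction_lrt(cc, m, mod, covariates = tiers$plus_lipid)
    data.frame(marker = m, modifier = mod, lrt = lrt$lrt_statistic,
               df = lrt$df, p = lrt$p_value)
  }))))
save_table(ints, out, "interaction_tests.csv")
print(fifths[fifths$marker == "tpa_log_base",
             c("fifth", "or", "ci_low", "ci_high")], digits = 3)
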