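#!/usr/bin/env Rscript
# Meta-analysis: simulate sets of published study estimates reported on
# heterogeneous scales, harmonize them to the per-1-SD scale, and write
# forest, funnel, meta-regression, Egger and subgroup tables.

source(file.path("analysis", "00_common.R"))
seed <- parse_seed()

est <- rbind(
  transform(generate_study_estimates(13, true_log_rr_per_sd = log(1.13),
                                     tau2 = 0.005, seed = seed),
            marker = "tpa"),
  transform(generate_study_estimates(18, true_log_rr_per_sd = log(1.23),
                                     tau2 = 0.010, seed = seed + 1L),
            marker = "ddimer"),
  transform(generate_study_estimates(9, true_log_rr_per_sd = log(1.16),
                                     tau2 = 0.008, seed = seed + 2L),
            marker = "vwf"))

out <- results_dir("meta")
write_estimates_csv(est, file.path(out, "study_estimates.csv"))
invisible(run_meta_analysis(out, est, seed = seed))

forest <- utils::read.csv(file.path(out, "forest.csv"))
print(forest[forest$is_summary,
             c("marker", "rr", "ci_low", "ci_high", "n_cases")],
      digits = 3)
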