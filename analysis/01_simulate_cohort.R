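#!/usr/bin/env Rscript
# Simulate the synthetic cohort at the default study conditions and write the
# participant table and the generating specification to results/data/.

source(file.path("analysis", "00_common.R"))
seed <- parse_seed()

spec <- cohort_spec(seed = seed)
cohort <- generate_cohort(spec)

out <- results_dir("data")
write_participants_csv(cohort, file.path(out, "participants.csv"))
write_cohort_spec(spec, file.path(out, "cohort_spec.yaml"))

message("cohort: n = ", nrow(cohort),
        ", incident cases = ", sum(cohort$is_case),
        ", repeat-measurement subsample = ",
        sum(!is.na(cohort$tpa_log_rep)))
message("wrote ", file.path(out, "participants.csv"), " and ",
        file.path(out, "cohort_spec.yaml"))
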