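# Shared helpers for the numbered analysis drivers.  Each driver is run from
# the repository root, e.g.:
#   Rscript analysis/01_simulate_cohort.R --seed 1
# and writes its tables under results/.

suppressPackageStartupMessages(library(hemocc))

parse_seed <- function(default = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i) == 1 && i < length(args)) return(as.integer(args[i + 1]))
  default
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

load_cohort <- function() {
  path <- file.path("results", "data", "participants.csv")
  if (!file.exists(path))
    stop("run analysis/01_simulate_cohort.R first (missing ", path, ")")
  read_participants_csv(path)
}

# the nested case-control sample is re-drawn deterministically from the seed,
# so downstream drivers agree without passing files around
load_case_control <- function(cohort, seed) {
  case_control_data(cohort,
                    sample_nested_case_control(cohort, ratio = 1.88,
                                               seed = seed))
}

save_table <- function(d, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(d, path, row.names = FALSE)
  message("wrote ", path, " (", nrow(d), " rows)")
  invisible(path)
}
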