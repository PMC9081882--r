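# Shared configuration for the analysis drivers.  Source'd by each step.
library(fosnet)

cfg <- list(
  seed = 20260920L,       # master seed for the whole workflow
  n_animals = 8L,         # animals per condition, the study's cohort size
  alpha = 0.05,           # uncorrected edge significance threshold
  results_dir = "results",
  cohort_dir = file.path("results", "cohorts")
)
dir.create(cfg$cohort_dir, recursive = TRUE, showWarnings = FALSE)
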