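#!/usr/bin/env Rscript
# Step 1: simulate the two-condition cohort pair.
#
# The study's raw density tables are not public, so the workflow runs on
# the study-emulation preset: two conditions of 8 animals over the
# 30-region lateralized atlas, the stimulated condition carrying planted
# global, inter-hemispheric and locus-coeruleus coupling increments.

source(file.path("analysis", "00_config.R"))

pair <- study_preset(n_animals = cfg$n_animals, seed = cfg$seed)
d <- generate_condition_pair(pair)

write_cohort(d$cohort_a, file.path(cfg$cohort_dir, "no_stim.csv"))
write_cohort(d$cohort_b, file.path(cfg$cohort_dir, "stim.csv"))

# ground-truth planted pairs, for recovery scoring downstream
truth_edges <- function(tm) {
  idx <- which(tm & upper.tri(tm), arr.ind = TRUE)
  data.frame(from = rownames(tm)[idx[, 1]], to = colnames(tm)[idx[, 2]])
}
jsonlite::write_json(
  list(truth_no_stim = truth_edges(d$truth_a),
       truth_stim = truth_edges(d$truth_b),
       effects = as.list(pair$effects),
       seed = cfg$seed, n_animals = cfg$n_animals),
  file.path(cfg$results_dir, "ground_truth.json"),
  auto_unbox = TRUE, digits = NA, dataframe = "rows")

cat("Simulated cohorts:", cfg$n_animals, "animals x", nrow(d$cohort_a$atlas),
    "regions per condition\n")
cat("Planted pairs:", sum(d$truth_a & upper.tri(d$truth_a)), "(no_stim),",
    sum(d$truth_b & upper.tri(d$truth_b)), "(stim)\n")
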