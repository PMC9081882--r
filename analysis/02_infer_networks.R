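#!/usr/bin/env Rscript
# Step 2: infer per-condition functional networks.
#
# For each condition: pairwise Spearman correlations across animals
# (exact permutation p-values at n = 8), thresholding at p < alpha, and
# Fisher-z strengths for the significant positive edges.  Writes the
# correlation matrices, signed edge lists, z-weight matrices and GraphML.

source(file.path("analysis", "00_config.R"))

for (cond in c("no_stim", "stim")) {
  cohort <- read_cohort(file.path(cfg$cohort_dir, paste0(cond, ".csv")))
  corr <- correlation_matrix(cohort)
  net <- suppressWarnings(threshold_network(corr, alpha = cfg$alpha))
  write_network_artifacts(corr, net, file.path(cfg$results_dir, "networks"),
                          prefix = cond)
  cat(sprintf(
    "%s: %d/435 significant edges (%d positive, %d negative), %.0f%% positive rho\n",
    cond, nrow(net$edges), sum(net$edges$sign > 0), sum(net$edges$sign < 0),
    100 * positive_fraction(corr)))
}
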