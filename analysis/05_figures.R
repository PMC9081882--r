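#!/usr/bin/env Rscript
# Step 5: figures.
#
# Chord-style circular diagrams of the signed significant networks
# (positive blue, negative red; p < 0.01 orange, p < 0.001 yellow) and
# Kamada-Kawai layouts of the positive z-weight graphs.  PNG and SVG.

source(file.path("analysis", "00_config.R"))

fig_dir <- file.path(cfg$results_dir, "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

nets <- lapply(c(no_stim = "no_stim", stim = "stim"), function(cond) {
  cohort <- read_cohort(file.path(cfg$cohort_dir, paste0(cond, ".csv")))
  suppressWarnings(threshold_network(correlation_matrix(cohort),
                                     alpha = cfg$alpha))
})

render <- function(open_dev, ext) {
  for (cond in names(nets)) {
    open_dev(file.path(fig_dir, paste0("chord_", cond, ext)))
    plot_network_chord(nets[[cond]])
    grDevices::dev.off()
    open_dev(file.path(fig_dir, paste0("kamada_kawai_", cond, ext)))
    plot_network_kk(nets[[cond]], seed = cfg$seed)
    grDevices::dev.off()
  }
}
render(function(f) grDevices::png(f, width = 900, height = 900, res = 120),
       ".png")
render(function(f) grDevices::svg(f, width = 7.5, height = 7.5), ".svg")

cat("Wrote", length(list.files(fig_dir)), "figures to", fig_dir, "\n")
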