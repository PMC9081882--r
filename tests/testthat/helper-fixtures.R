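# Small in-code fixtures shared across test files.

# A cohort with fully independent regions, continuous densities (no ties).
make_null_cohort <- function(n_animals = 8, seed = 1, condition = "null") {
  generate_cohort(synthetic_spec(n_animals = n_animals, seed = seed,
                                 condition = condition))
}

# A tiny 4-region atlas for hand-checkable cases.
tiny_atlas <- function() {
  validate_atlas(data.frame(
    code = c("Cg-L", "Cg-R", "DG-L", "DG-R"),
    name = c("cingulate cortex", "cingulate cortex",
             "dentate gyrus", "dentate gyrus"),
    hemisphere = c("left", "right", "left", "right"),
    display_group = c("cortical", "cortical", "hippocampal", "hippocampal"),
    area_group = c("frontal", "frontal", "hippocampal", "hippocampal"),
    stringsAsFactors = FALSE), require_default_size = FALSE)
}

# Build a fos_network directly from an explicit edge list (for the
# hemispheric-count unit tests).
network_from_edges <- function(edges, atlas = default_atlas(),
                               alpha = 0.05) {
  p <- nrow(atlas)
  zw <- matrix(0, p, p, dimnames = list(atlas$code, atlas$code))
  if (nrow(edges)) {
    pos <- edges$sign > 0
    idx <- cbind(match(edges$from, atlas$code), match(edges$to, atlas$code))
    zw[idx[pos, , drop = FALSE]] <- atanh(edges$rho[pos])
    zw[idx[pos, 2:1, drop = FALSE]] <- atanh(edges$rho[pos])
  }
  structure(list(edges = edges, z_weights = zw, alpha = alpha,
                 adjust = "none", atlas = atlas, condition = "manual"),
            class = "fos_network")
}

empty_edge_df <- function() {
  data.frame(from = character(), to = character(), rho = numeric(),
             p = numeric(), n = integer(), sign = integer(),
             stringsAsFactors = FALSE)
}
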