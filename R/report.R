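# Artifact output: CSV / GraphML network interchange and JSON reports.
# GraphML carries the weighted undirected graph with per-edge statistics;
# CSV mirrors exist for spreadsheet use.  All numeric output keeps at
# least 10 significant digits.

#' Convert a functional network to an igraph object
#'
#' Nodes are atlas regions (with hemisphere and group attributes); edges
#' are the significant correlations of either sign, carrying `rho`, `p`,
#' `sign` and `weight` (Fisher z for positive edges, 0 for negative ones).
#'
#' @param net A `fos_network`.
#' @param positive_only Keep only significant positive edges (the graph the
#'   weighted metrics are computed on).  Default `FALSE`.
#' @return An igraph graph.
#' @export
as_igraph <- function(net, positive_only = FALSE) {
  stopifnot(inherits(net, "fos_network"))
  e <- net$edges
  if (positive_only) e <- e[e$sign > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = net$atlas$code,
                          hemisphere = net$atlas$hemisphere,
                          display_group = net$atlas$display_group,
                          area_group = net$atlas$area_group,
                          stringsAsFactors = FALSE))
  if (nrow(e)) {
    igraph::E(g)$rho <- e$rho
    igraph::E(g)$p <- e$p
    igraph::E(g)$sign <- e$sign
    igraph::E(g)$weight <- ifelse(e$sign > 0, atanh(pmin(e$rho, 1 - 1e-7)), 0)
  }
  g
}

#' Write network artifacts for one condition
#'
#' Emits `<prefix>_rho.csv`, `<prefix>_pvals.csv` (full symmetric
#' matrices), `<prefix>_edges.csv` (signed significant edge list),
#' `<prefix>_zweights.csv` (positive Fisher-z weight matrix) and
#' `<prefix>_network.graphml`.
#'
#' @param corr A `fos_corr`.
#' @param net The matching `fos_network`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix, default the condition label.
#' @return Character vector of the files written, invisibly.
#' @export
write_network_artifacts <- function(corr, net, dir,
                                    prefix = net$condition) {
  stopifnot(inherits(corr, "fos_corr"), inherits(net, "fos_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(dir, paste0(prefix, "_", name))
  wmat <- function(m, path)
    utils::write.csv(format(as.data.frame(m), digits = 12, trim = TRUE),
                     path, row.names = TRUE)
  wmat(corr$rho, f("rho.csv"))
  wmat(corr$pvals, f("pvals.csv"))
  wmat(net$z_weights, f("zweights.csv"))
  utils::write.csv(net$edges, f("edges.csv"), row.names = FALSE)
  igraph::write_graph(as_igraph(net), f("network.graphml"),
                      format = "graphml")
  invisible(vapply(c("rho.csv", "pvals.csv", "zweights.csv", "edges.csv",
                     "network.graphml"), f, character(1)))
}

#' Write a JSON analysis report for a two-condition contrast
#'
#' Serializes the global metrics and hub rankings per condition, the total
#' and LC connectivity contrasts, hemispheric counts, positive fractions
#' and per-region density tests.
#'
#' @param contrast A `fos_contrast` from [compare_conditions()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_contrast_report <- function(contrast, path) {
  stopifnot(inherits(contrast, "fos_contrast"))
  pick_metrics <- function(m)
    list(global_efficiency = m$global_efficiency,
         average_clustering = m$average_clustering,
         average_strength = m$average_strength,
         average_degree = m$average_degree,
         nodal = m$nodal,
         hub_order_strength = m$hub_order_strength,
         hub_order_degree = m$hub_order_degree)
  out <- list(
    conditions = c(contrast$label_a, contrast$label_b),
    metrics = list(a = pick_metrics(contrast$metrics_a),
                   b = pick_metrics(contrast$metrics_b)),
    total_connectivity = contrast$total_connectivity,
    lc_contrast = contrast$lc_contrast,
    hemispheric_counts = contrast$hemispheric_counts,
    positive_fraction = as.list(contrast$positive_fraction),
    density_tests = contrast$density_tests)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
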