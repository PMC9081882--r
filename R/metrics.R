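# Weighted-undirected graph metrics following Brain Connectivity Toolbox
# conventions: edge lengths are inverse weights for efficiency, and the
# clustering coefficient is Onnela's geometric-mean-of-triangles form on
# weights normalized by the network-wide maximum.

#' Construct a weighted undirected graph
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal; row
#'   and column names are the node labels.
#' @param nodes Optional node labels (defaults to `colnames(W)`).
#' @return An object of class `fos_graph` wrapping the validated matrix.
#' @export
weighted_graph <- function(W, nodes = colnames(W)) {
  W <- as.matrix(W)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(ncol(W)))
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (anyNA(W)) stop("weight matrix must not contain NA")
  if (any(W < 0)) stop("weights must be non-negative")
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)))
    stop("weight matrix must be symmetric")
  W <- (W + t(W)) / 2
  if (any(diag(W) != 0)) stop("diagonal (self-weights) must be zero")
  dimnames(W) <- list(nodes, nodes)
  structure(list(W = W, nodes = nodes), class = "fos_graph")
}

#' Extract the positive-strength graph of a functional network
#'
#' The weighted graph on which the global and nodal metrics are evaluated:
#' nodes are atlas regions, weights the Fisher-z strengths of significant
#' positive correlations.
#'
#' @param net A `fos_network` from [threshold_network()].
#' @return A `fos_graph`.
#' @export
network_graph <- function(net) {
  stopifnot(inherits(net, "fos_network"))
  weighted_graph(net$z_weights)
}

as_fos_graph <- function(G) {
  if (inherits(G, "fos_graph")) G
  else if (inherits(G, "fos_network")) network_graph(G)
  else weighted_graph(G)
}

#' Nodal degree
#'
#' Number of incident edges (positive-weight neighbours) per node.
#'
#' @param G A `fos_graph`, `fos_network`, or weight matrix.
#' @return Named integer vector.
#' @export
nodal_degree <- function(G) {
  W <- as_fos_graph(G)$W
  rowSums(W > 0)
}

#' Nodal strength
#'
#' Sum of incident edge weights per node.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector.
#' @export
nodal_strength <- function(G) {
  W <- as_fos_graph(G)$W
  rowSums(W)
}

#' Onnela weighted clustering coefficient
#'
#' Weights are first normalized by the network-wide maximum,
#' `w' = W / max(W)`; each node's coefficient is the geometric mean of
#' triangle weights around it,
#' `C_i = sum_(j,h) (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))`,
#' with `C_i = 0` for nodes of degree < 2.
#'
#' @inheritParams nodal_degree
#' @return List with `per_node` (named vector) and `average` (mean over all
#'   nodes, isolated nodes included as zero).
#' @export
clustering_weighted <- function(G) {
  W <- as_fos_graph(G)$W
  n <- ncol(W)
  k <- rowSums(W > 0)
  mx <- max(W)
  if (mx == 0) {
    per <- stats::setNames(numeric(n), colnames(W))
    return(list(per_node = per, average = 0))
  }
  A <- (W / mx)^(1 / 3)
  cyc <- diag(A %*% A %*% A)     # 2 * weighted triangles around each node
  per <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  names(per) <- colnames(W)
  list(per_node = per, average = mean(per))
}

#' Weighted global efficiency
#'
#' Positive weights are mapped to lengths `L_ij = 1 / W_ij`; shortest-path
#' distances `d_ij` are computed over these lengths and
#' `E = mean over ordered pairs of 1 / d_ij`, with unreachable pairs
#' contributing zero (they are kept in the average, not dropped).
#'
#' @inheritParams nodal_degree
#' @return Scalar efficiency, >= 0.
#' @export
global_efficiency <- function(G) {
  W <- as_fos_graph(G)$W
  n <- ncol(W)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wts <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(wts)) 1 / wts else numeric(0))
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global and nodal metric report for a network
#'
#' Computes the four global metrics (global efficiency, average clustering,
#' average strength, average degree — all means over nodes), the per-node
#' strength and degree, their max-normalized versions (an all-zero vector
#' stays zero), and hub rankings: nodes ordered by descending normalized
#' strength (ties broken by normalized degree, then atlas order) and,
#' separately, by descending normalized degree.
#'
#' @inheritParams nodal_degree
#' @return An object of class `fos_metrics`: list with scalars
#'   `global_efficiency`, `average_clustering`, `average_strength`,
#'   `average_degree`; data frame `nodal` (`code`, `degree`, `strength`,
#'   `clustering`, `norm_degree`, `norm_strength`); and character vectors
#'   `hub_order_strength`, `hub_order_degree`.
#' @export
summarize_network <- function(G) {
  g <- as_fos_graph(G)
  k <- nodal_degree(g)
  s <- nodal_strength(g)
  cl <- clustering_weighted(g)
  norm0 <- function(v) if (max(v) > 0) v / max(v) else v
  nk <- norm0(k); ns <- norm0(s)
  nodal <- data.frame(code = g$nodes, degree = as.integer(k), strength = s,
                      clustering = cl$per_node, norm_degree = nk,
                      norm_strength = ns, row.names = NULL,
                      stringsAsFactors = FALSE)
  ord_s <- order(-ns, -nk, seq_along(ns))
  ord_k <- order(-nk, -ns, seq_along(nk))
  structure(list(
    global_efficiency = global_efficiency(g),
    average_clustering = cl$average,
    average_strength = mean(s),
    average_degree = mean(k),
    nodal = nodal,
    hub_order_strength = g$nodes[ord_s],
    hub_order_degree = g$nodes[ord_k]),
    class = "fos_metrics")
}

#' @export
print.fos_metrics <- function(x, ...) {
  cat("Weighted network metrics\n")
  cat(sprintf("  global efficiency:  %.4f\n", x$global_efficiency))
  cat(sprintf("  average clustering: %.4f\n", x$average_clustering))
  cat(sprintf("  average strength:   %.4f\n", x$average_strength))
  cat(sprintf("  average degree:     %.4f\n", x$average_degree))
  cat("  top hubs (by strength):",
      paste(utils::head(x$hub_order_strength, 5), collapse = ", "), "\n")
  invisible(x)
}
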