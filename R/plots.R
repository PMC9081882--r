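# Figures: a chord-style circular edge diagram of the signed significant
# network, and a Kamada-Kawai force-directed layout of the positive
# z-weight graph.  Base graphics; layouts carry no analytic weight.

fos_group_colors <- c(cortical = "#E69F00", hippocampal = "#9467BD",
                      amygdalar = "#D62728", thalamic = "#2CA02C",
                      brainstem = "#1F77B4")

#' Chord diagram of a functional network
#'
#' Regions are placed on a circle frontal to caudal with the two
#' hemispheres on opposite halves.  Significant positive edges are drawn
#' in blue and negative edges in red; the strongest edges are highlighted
#' in orange (p < 0.01) and yellow (p < 0.001).  Node points are colored
#' by anatomical display group.
#'
#' @param net A `fos_network`.
#' @param main Plot title (defaults to the condition label).
#' @return Invisibly, the data frame of node positions.
#' @export
plot_network_chord <- function(net, main = net$condition) {
  stopifnot(inherits(net, "fos_network"))
  atlas <- net$atlas
  left <- atlas$code[atlas$hemisphere == "left"]
  right <- atlas$code[atlas$hemisphere == "right"]
  # left hemisphere down the left half (top to bottom), right mirrored
  nl <- length(left); nr <- length(right)
  th_l <- pi / 2 + pi * (seq_len(nl) - 0.5) / nl
  th_r <- pi / 2 - pi * (seq_len(nr) - 0.5) / nr
  pos <- rbind(
    data.frame(code = left, theta = th_l, stringsAsFactors = FALSE),
    data.frame(code = right, theta = th_r, stringsAsFactors = FALSE))
  pos$x <- cos(pos$theta); pos$y <- sin(pos$theta)
  pos$group <- atlas$display_group[match(pos$code, atlas$code)]

  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  e <- net$edges
  if (nrow(e)) {
    col <- ifelse(e$sign > 0, "#3B6FB6", "#C23B3B")
    col[e$p < 0.01] <- "#E8821E"
    col[e$p < 0.001] <- "#E8C51E"
    ord <- order(-e$p)       # strongest (smallest p) drawn last, on top
    for (k in ord) {
      p1 <- pos[pos$code == e$from[k], c("x", "y")]
      p2 <- pos[pos$code == e$to[k], c("x", "y")]
      # quadratic Bezier pulled toward the centre
      tt <- seq(0, 1, length.out = 40)
      bx <- (1 - tt)^2 * p1$x + tt^2 * p2$x
      by <- (1 - tt)^2 * p1$y + tt^2 * p2$y
      graphics::lines(bx, by, col = col[k],
                      lwd = if (e$p[k] < 0.01) 2 else 1.2)
    }
  }
  graphics::points(pos$x, pos$y, pch = 21, cex = 1.6,
                   bg = fos_group_colors[pos$group])
  lab_r <- 1.18
  graphics::text(lab_r * pos$x, lab_r * pos$y, pos$code, cex = 0.55,
                 srt = 0)
  invisible(pos)
}

#' Kamada-Kawai layout of the positive z-weight network
#'
#' Force-directed drawing of the significant-positive-edge graph with edge
#' width proportional to Fisher-z strength and node color by anatomical
#' display group.  The layout is seeded for reproducibility and is
#' presentation only.
#'
#' @param net A `fos_network`.
#' @param seed Layout seed (default 1).
#' @param main Plot title (defaults to the condition label).
#' @return Invisibly, the layout coordinate matrix.
#' @export
plot_network_kk <- function(net, seed = 1L, main = net$condition) {
  stopifnot(inherits(net, "fos_network"))
  g <- as_igraph(net, positive_only = TRUE)
  lay <- withr::with_seed(seed, igraph::layout_with_kk(g))
  w <- igraph::E(g)$weight
  igraph::plot.igraph(
    g, layout = lay, main = main,
    vertex.color = fos_group_colors[igraph::V(g)$display_group],
    vertex.size = 9, vertex.label.cex = 0.55,
    vertex.label.color = "black",
    edge.width = if (length(w)) 1 + 2 * w / max(w, 1e-12) else 1)
  invisible(lay)
}
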