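# Minimal visualisation helpers (igraph-based).

#' Plot a state-transition graph
#'
#' Draws the STG with igraph; attractor states, when supplied, are
#' highlighted.
#'
#' @param x An \code{lddr_stg}.
#' @param attractors Optional result of [find_attractors()].
#' @param ... Passed to \code{igraph::plot.igraph}.
#' @export
plot.lddr_stg <- function(x, attractors = NULL, ...) {
  g <- igraph::graph_from_data_frame(x$transitions, directed = TRUE,
                                     vertices = names(x$states))
  cols <- rep("grey85", length(x$states))
  names(cols) <- names(x$states)
  if (!is.null(attractors))
    for (a in attractors)
      cols[a$states] <- if (a$kind == "STEADY_STATE") "tomato" else "gold"
  igraph::plot.igraph(g, vertex.color = cols[names(x$states)],
                      vertex.label.cex = 0.7, edge.arrow.size = 0.3, ...)
  invisible(x)
}

#' Plot a signed interaction graph
#'
#' Activating arcs solid, inhibiting arcs dashed.
#'
#' @param x An \code{lddr_graph}.
#' @param ... Passed to \code{igraph::plot.igraph}.
#' @export
plot.lddr_graph <- function(x, ...) {
  g <- as_igraph(x)
  lty <- ifelse(igraph::E(g)$sign < 0, 2L, 1L)
  igraph::plot.igraph(g, edge.lty = lty, edge.arrow.size = 0.4,
                      vertex.color = "lightsteelblue",
                      vertex.label.cex = 0.8, ...)
  invisible(x)
}

#' Dependency matrix as a colour-coded image
#'
#' Base-graphics heat map with the conventional colour code: dark green
#' strong activator, light green weak activator, dark red strong inhibitor,
#' pink weak inhibitor, yellow ambivalent, black no effect.
#'
#' @param x An \code{lddr_depmat}.
#' @param ... Passed to \code{graphics::image}.
#' @export
plot.lddr_depmat <- function(x, ...) {
  pal <- c(STRONG_ACTIVATOR = "darkgreen", WEAK_ACTIVATOR = "palegreen3",
           STRONG_INHIBITOR = "darkred", WEAK_INHIBITOR = "pink",
           AMBIVALENT = "gold", NO_EFFECT = "black")
  z <- matrix(match(unclass(x), names(pal)), nrow(x), ncol(x))
  graphics::image(seq_len(ncol(x)), seq_len(nrow(x)),
                  t(z[rev(seq_len(nrow(x))), , drop = FALSE]),
                  col = pal, zlim = c(1, 6), axes = FALSE,
                  xlab = "target j", ylab = "source i", ...)
  graphics::axis(1, at = seq_len(ncol(x)), labels = colnames(x), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(x)), labels = rev(rownames(x)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
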