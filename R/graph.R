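# Signed interaction graph: hyperarc splitting, SIF/GraphML export.

#' Signed interaction graph of a logical model
#'
#' Each hyperarc (term) is split into its constituent arcs, one per literal.
#' Arc sign = literal sign x term direction, where the literal sign is -1 for
#' negated literals and the term direction is +1 for terms with
#' \code{target_level >= 1} and -1 for explicit inactivation terms
#' (\code{target_level} 0), which reproduces T-arcs of inhibiting
#' interactions.
#'
#' @param model A \code{lddr_model}.
#' @param cutoff Time-scale cutoff; arcs from later terms are excluded
#'   (default 3 = all).
#' @return An object of class \code{lddr_graph}: a \code{data.frame} of arcs
#'   (source, target, sign, time_scale, term_id, threshold) with the node set
#'   as attribute \code{nodes}.
#' @export
interaction_graph <- function(model, cutoff = 3L) {
  rows <- list()
  for (t in model$terms) {
    if (t$time_scale > cutoff) next
    l <- t$literals
    if (!nrow(l)) next
    dir <- if (t$target_level >= 1L) 1L else -1L
    rows[[length(rows) + 1L]] <- data.frame(
      source = l$component, target = t$target,
      sign = ifelse(l$negated, -1L, 1L) * dir,
      time_scale = t$time_scale, term_id = t$id, threshold = l$threshold,
      stringsAsFactors = FALSE)
  }
  arcs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(), sign = integer(),
               time_scale = integer(), term_id = integer(),
               threshold = integer(), stringsAsFactors = FALSE)
  rownames(arcs) <- NULL
  signed_graph(arcs, nodes = model$components$name)
}

#' Construct a signed graph from an arc table
#' @param arcs \code{data.frame} with columns source, target, sign (+1/-1);
#'   optional time_scale, term_id, threshold.
#' @param nodes Node identifiers (defaults to those appearing in arcs).
#' @return An \code{lddr_graph}.
#' @export
signed_graph <- function(arcs, nodes = NULL) {
  for (col in c("time_scale", "term_id", "threshold"))
    if (is.null(arcs[[col]])) arcs[[col]] <- NA_integer_
  if (is.null(nodes)) nodes <- union(arcs$source, arcs$target)
  structure(arcs, nodes = as.character(nodes),
            class = c("lddr_graph", "data.frame"))
}

#' @export
print.lddr_graph <- function(x, ...) {
  cat(sprintf("Signed interaction graph: %d nodes, %d arcs (%d inhibiting)\n",
              length(attr(x, "nodes")), nrow(x), sum(x$sign < 0)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20L))
  invisible(x)
}

#' Nodes of a signed graph
#' @param graph An \code{lddr_graph}.
#' @export
graph_nodes <- function(graph) attr(graph, "nodes")

#' Export a signed graph as SIF text (Cytoscape dialect)
#'
#' One row per arc: \code{source<TAB>relation<TAB>target} with relation
#' \code{activates} or \code{inhibits}.
#'
#' @param graph An \code{lddr_graph}.
#' @param path Optional file path.
#' @return Character vector of rows (invisibly when \code{path} given).
#' @export
export_sif <- function(graph, path = NULL) {
  rel <- ifelse(graph$sign > 0, "activates", "inhibits")
  rows <- sprintf("%s\t%s\t%s", graph$source, rel, graph$target)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(rows, con, useBytes = TRUE)
    return(invisible(rows))
  }
  rows
}

#' Convert a signed graph to an igraph object
#' @param graph An \code{lddr_graph}.
#' @return An \code{igraph} directed graph with edge attributes sign,
#'   time_scale, term_id.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$source, to = graph$target, sign = graph$sign,
               time_scale = graph$time_scale, term_id = graph$term_id,
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = graph_nodes(graph))
}

#' Export a signed graph as GraphML text
#' @param graph An \code{lddr_graph}.
#' @param path Optional file path.
#' @return GraphML document as one string (invisibly when \code{path} given).
#' @export
export_graphml <- function(graph, path = NULL) {
  g <- as_igraph(graph)
  tmp <- tempfile(fileext = ".graphml")
  on.exit(unlink(tmp))
  igraph::write_graph(g, tmp, format = "graphml")
  txt <- paste(readLines(tmp, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
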