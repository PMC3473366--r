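# Structural analyses: parity reachability, dependency matrix,
# feed-forward loops, feedback loops and their functionality contexts.

#' Signed (parity) reachability between all node pairs
#'
#' Fixpoint over the (node, parity) product graph: a path's sign is the
#' product of its arc signs; paths have length >= 1, so the diagonal reports
#' closed paths through the node. Revisits are allowed (walk semantics); see
#' [simple_path_signs()] for the stricter notion the dependency matrix uses.
#'
#' @param graph An \code{lddr_graph}.
#' @return List with logical matrices \code{positive} and \code{negative}
#'   (rows = source, cols = target).
#' @export
signed_reachability <- function(graph) {
  nodes <- graph_nodes(graph)
  n <- length(nodes)
  pos <- neg <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (!nrow(graph) || n == 0L)
    return(list(positive = pos, negative = neg))
  si <- match(graph$source, nodes)
  ti <- match(graph$target, nodes)
  sg <- graph$sign
  # adjacency lists
  adj <- vector("list", n)
  for (k in seq_along(si))
    adj[[si[k]]] <- rbind(adj[[si[k]]], c(ti[k], sg[k]))
  for (i in seq_len(n)) {
    # BFS over (node, parity); parity +1 / -1
    reach <- matrix(FALSE, n, 2L)  # col 1 = +, col 2 = -
    queue <- list()
    push <- function(v, p) {
      col <- if (p > 0) 1L else 2L
      if (!reach[v, col]) {
        reach[v, col] <<- TRUE
        queue[[length(queue) + 1L]] <<- c(v, p)
      }
    }
    if (!is.null(adj[[i]]))
      for (k in seq_len(nrow(adj[[i]])))
        push(adj[[i]][k, 1L], adj[[i]][k, 2L])
    while (length(queue)) {
      cur <- queue[[1L]]; queue[[1L]] <- NULL
      v <- cur[1L]; p <- cur[2L]
      if (!is.null(adj[[v]]))
        for (k in seq_len(nrow(adj[[v]])))
          push(adj[[v]][k, 1L], p * adj[[v]][k, 2L])
    }
    pos[i, ] <- reach[, 1L]
    neg[i, ] <- reach[, 2L]
  }
  list(positive = pos, negative = neg)
}

#' Nodes lying on a negative cycle
#'
#' A node is regulated by a negative feedback loop when it lies on at least
#' one simple cycle whose arc-sign product is negative.
#'
#' @param graph An \code{lddr_graph}.
#' @param spr Optional precomputed [simple_path_signs()] result.
#' @return Named logical vector over nodes.
#' @export
on_negative_cycle <- function(graph, spr = NULL) {
  if (is.null(spr)) spr <- simple_path_signs(graph)
  diag(spr$negative)
}

#' Sign-wise simple-path reachability
#'
#' For every ordered pair (i, j) reports whether a positive and whether a
#' negative \emph{simple} path (no repeated nodes) i -> j exists; the
#' diagonal reports simple cycles through the node. Unlike
#' [signed_reachability()], walks that revisit a node (e.g. absorbing a
#' negative loop hanging off a pathway) do not count: this is the path
#' notion under which a component can be a weak — rather than ambivalent —
#' regulator of another. Exhaustive in the worst case; intended for the
#' sparse graphs of curated signalling models.
#'
#' @param graph An \code{lddr_graph}.
#' @return List with logical matrices \code{positive} and \code{negative}.
#' @export
simple_path_signs <- function(graph) {
  nodes <- graph_nodes(graph)
  n <- length(nodes)
  pos <- neg <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (!nrow(graph) || n == 0L)
    return(list(positive = pos, negative = neg))
  arcs_by_src <- split(seq_len(nrow(graph)), graph$source)
  for (i in seq_len(n)) {
    src <- nodes[i]
    dfs <- function(cur, sign, visited) {
      for (k in arcs_by_src[[cur]]) {
        tgt <- graph$target[k]
        s <- sign * graph$sign[k]
        if (tgt == src) {
          # simple cycle through the source
          if (s > 0) pos[i, i] <<- TRUE else neg[i, i] <<- TRUE
          next
        }
        if (tgt %in% visited) next
        ti <- match(tgt, nodes)
        if (s > 0) pos[i, ti] <<- TRUE else neg[i, ti] <<- TRUE
        dfs(tgt, s, c(visited, tgt))
      }
    }
    dfs(src, 1L, src)
  }
  list(positive = pos, negative = neg)
}

.DEP_CLASSES <- c("STRONG_ACTIVATOR", "WEAK_ACTIVATOR", "STRONG_INHIBITOR",
                  "WEAK_INHIBITOR", "AMBIVALENT", "NO_EFFECT")

#' Dependency matrix
#'
#' Classifies every ordered component pair (i, j): \code{NO_EFFECT} when no
#' simple path i -> j exists; \code{AMBIVALENT} when both positive and
#' negative simple paths exist; otherwise an activator (only positive paths)
#' or inhibitor (only negative paths), \code{STRONG} when no species on any
#' i -> j path — the endpoints included — lies on a negative feedback loop,
#' else \code{WEAK}. Path signs use simple-path semantics
#' ([simple_path_signs()]): a negative loop hanging off an otherwise positive
#' pathway makes the dependency weak, not ambivalent. The diagonal is
#' classified by the simple cycles through the node (no cycle through i
#' gives \code{NO_EFFECT}).
#'
#' @param graph An \code{lddr_graph}.
#' @return Character matrix of the six class strings, class
#'   \code{lddr_depmat}.
#' @export
dependency_matrix <- function(graph) {
  nodes <- graph_nodes(graph)
  n <- length(nodes)
  spr <- simple_path_signs(graph)
  reach <- signed_reachability(graph)
  any_reach <- reach$positive | reach$negative
  on_neg <- on_negative_cycle(graph, spr)
  m <- matrix("NO_EFFECT", n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- spr$positive[i, j]; q <- spr$negative[i, j]
    if (!p && !q) next
    if (p && q) { m[i, j] <- "AMBIVALENT"; next }
    # nodes on some i -> j walk, endpoints included
    mid <- which(any_reach[i, ] & any_reach[, j])
    onpath <- union(mid, c(i, j))
    weak <- any(on_neg[onpath])
    m[i, j] <- if (p) {
      if (weak) "WEAK_ACTIVATOR" else "STRONG_ACTIVATOR"
    } else {
      if (weak) "WEAK_INHIBITOR" else "STRONG_INHIBITOR"
    }
  }
  structure(m, class = c("lddr_depmat", "matrix"))
}

#' @export
print.lddr_depmat <- function(x, ...) {
  cat(sprintf("Dependency matrix (%d x %d)\n", nrow(x), ncol(x)))
  tab <- table(factor(unclass(x), levels = .DEP_CLASSES))
  print(tab)
  invisible(x)
}

# sign sets per ordered node pair: list keyed "src\x01tgt" -> unique signs
.arc_sign_sets <- function(graph) {
  key <- paste(graph$source, graph$target, sep = "\x01")
  tapply(graph$sign, key, function(s) sort(unique(s)), simplify = FALSE)
}

#' Enumerate feed-forward loops with type and gate classification
#'
#' A feed-forward loop (FFL) is an ordered triple x, y, z of distinct nodes
#' with arcs x -> y, y -> z and x -> z. Parallel arcs collapse to one record
#' per sign combination. Coherence: \code{COHERENT} iff the direct sign equals
#' the product of the indirect signs. Type index follows the Mangan-Alon
#' convention on (s_xy, s_yz): (+,+) type 1, (-,-) type 2, (+,-) type 3,
#' (-,+) type 4. The gate of z is \code{AND} when the x- and y-literals
#' co-occur in one term of z, \code{OR} when they occur only in distinct
#' terms, \code{MIXED} otherwise.
#'
#' @param model A \code{lddr_model}.
#' @return \code{data.frame} with columns x, y, z, s_xy, s_yz, s_xz,
#'   coherence, type_index, gate.
#' @export
enumerate_ffls <- function(model) {
  graph <- interaction_graph(model)
  signs <- .arc_sign_sets(graph)
  pairs <- unique(graph[, c("source", "target")])
  out_of <- split(pairs$target, pairs$source)
  empty <- data.frame(x = character(), y = character(), z = character(),
                      s_xy = integer(), s_yz = integer(), s_xz = integer(),
                      coherence = character(), type_index = integer(),
                      gate = character(), stringsAsFactors = FALSE)
  rows <- list()
  for (x in names(out_of)) {
    for (y in setdiff(out_of[[x]], x)) {
      zs <- intersect(setdiff(out_of[[y]], c(x, y)), out_of[[x]])
      for (z in zs) {
        for (s_xy in signs[[paste(x, y, sep = "\x01")]])
          for (s_yz in signs[[paste(y, z, sep = "\x01")]])
            for (s_xz in signs[[paste(x, z, sep = "\x01")]]) {
              coh <- if (s_xz == s_xy * s_yz) "COHERENT" else "INCOHERENT"
              ti <- if (s_xy > 0 && s_yz > 0) 1L else
                if (s_xy < 0 && s_yz < 0) 2L else
                  if (s_xy > 0) 3L else 4L
              rows[[length(rows) + 1L]] <- data.frame(
                x = x, y = y, z = z, s_xy = s_xy, s_yz = s_yz, s_xz = s_xz,
                coherence = coh, type_index = ti,
                gate = .ffl_gate(model, graph, x, y, z, s_xz, s_yz),
                stringsAsFactors = FALSE)
            }
      }
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res[order(res$x, res$y, res$z, res$s_xy, res$s_yz, res$s_xz), ,
      drop = FALSE]
}

# gate of z for inputs x (arc sign sx) and y (arc sign sy)
.ffl_gate <- function(model, graph, x, y, z, sx, sy) {
  # term ids of z containing an x-literal realizing sign sx / y-literal sign sy
  match_term_ids <- function(src, s) {
    sel <- graph$source == src & graph$target == z & graph$sign == s
    unique(graph$term_id[sel])
  }
  tx <- match_term_ids(x, sx)
  ty <- match_term_ids(y, sy)
  both <- intersect(tx, ty)
  only_x <- setdiff(tx, ty)
  only_y <- setdiff(ty, tx)
  if (length(both) && !length(only_x) && !length(only_y)) "AND"
  else if (!length(both) && length(only_x) && length(only_y)) "OR"
  else "MIXED"
}

#' Enumerate simple feedback loops up to a length bound
#'
#' All simple cycles (self-loops included) of at most \code{max_length}
#' nodes, with their sign = product of member-arc signs. Where parallel arcs
#' of both signs exist along a cycle, one record per achievable sign is
#' emitted.
#'
#' @param graph An \code{lddr_graph}.
#' @param max_length Maximum cycle length (default 8).
#' @return List of feedback loops: each \code{list(nodes =, sign =)}, nodes in
#'   canonical rotation (starting at the lexicographically smallest node).
#' @export
enumerate_feedback_loops <- function(graph, max_length = 8L) {
  stopifnot(max_length >= 1L)
  nodes <- sort(graph_nodes(graph))
  signs <- .arc_sign_sets(graph)
  succ <- split(unique(graph[, c("source", "target")])$target,
                unique(graph[, c("source", "target")])$source)
  loops <- list()
  emit <- function(path, sign)
    loops[[length(loops) + 1L]] <<- list(nodes = path,
                                         sign = as.integer(sign))
  for (start in nodes) {
    # DFS over nodes >= start (cycle canonically starts at its smallest node)
    dfs <- function(path, sign_set) {
      last <- path[length(path)]
      for (nxt in succ[[last]]) {
        if (is.null(nxt)) next
        arc_signs <- signs[[paste(last, nxt, sep = "\x01")]]
        if (nxt == start) {
          for (s in sign_set) for (a in arc_signs) emit(path, s * a)
        } else if (nxt > start && !(nxt %in% path) &&
                   length(path) < max_length) {
          new_signs <- sort(unique(as.vector(outer(sign_set, arc_signs))))
          dfs(c(path, nxt), new_signs)
        }
      }
    }
    if (!is.null(succ[[start]])) dfs(start, 1L)
  }
  # dedupe identical (nodes, sign) records
  key <- vapply(loops, function(l) paste(c(l$nodes, l$sign), collapse = "\x01"),
                character(1))
  loops <- loops[!duplicated(key)]
  loops[order(vapply(loops, function(l) length(l$nodes), integer(1)),
              vapply(loops, function(l) paste(l$nodes, collapse = "\x01"),
                     character(1)),
              vapply(loops, function(l) l$sign, integer(1)))]
}

#' Functionality contexts of a feedback loop
#'
#' The functionality context of a loop is a set of constraints on its
#' external regulators (components that regulate a loop member but are not
#' themselves on the loop). Under a given assignment of the external
#' regulators, an arc u -> v of the loop is functional when toggling u across
#' some threshold changes the resolved target level of v for some assignment
#' of v's remaining loop-member regulators; the loop is functional in that
#' context when every loop arc is functional. The context-dependent loop sign
#' is the product of the arc derivative signs (NA when an arc's derivative
#' sign is not uniform within the context).
#'
#' @param model A \code{lddr_model}.
#' @param loop A loop from [enumerate_feedback_loops()] (or
#'   \code{list(nodes = ...)}).
#' @param context_cap Maximum number of external-regulator assignments to
#'   enumerate (guard; default 59049 = 3^10).
#' @return \code{data.frame} with one row per functional context: the
#'   external regulator levels plus a \code{.sign} column; zero rows when the
#'   loop is non-functional. External-regulator names are stored in attribute
#'   \code{externals}.
#' @export
functionality_context <- function(model, loop, context_cap = 59049L) {
  nodes <- loop$nodes
  comp <- model$components
  maxlev <- stats::setNames(comp$max_level, comp$name)
  stopifnot(all(nodes %in% comp$name))
  regs_of <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(unlist(lapply(.terms_for(model, v), function(t)
      t$literals$component))))
  ext <- sort(setdiff(unique(unlist(regs_of)), nodes))
  n_ctx <- prod(maxlev[ext] + 1)
  if (length(ext) && n_ctx > context_cap)
    stop(sprintf("context space too large (%g assignments)", n_ctx),
         call. = FALSE)
  ctx_grid <- if (length(ext))
    do.call(expand.grid, c(lapply(ext, function(e) 0:maxlev[[e]]),
                           KEEP.OUT.ATTRS = FALSE))
  else data.frame(row.names = 1L)
  if (length(ext)) names(ctx_grid) <- ext

  arcs <- cbind(nodes, c(nodes[-1L], nodes[1L]))  # u -> v around the loop
  res <- list()
  for (r in seq_len(nrow(ctx_grid))) {
    K <- if (length(ext)) stats::setNames(as.integer(ctx_grid[r, ]), ext)
    else integer()
    arc_signs <- rep(NA_integer_, nrow(arcs))
    functional <- TRUE
    for (a in seq_len(nrow(arcs))) {
      u <- arcs[a, 1L]; v <- arcs[a, 2L]
      s <- .arc_derivative_sign(model, u, v, K, regs_of[[v]], maxlev)
      if (!is.na(s) && s == 0L) { functional <- FALSE; break }
      arc_signs[a] <- s  # NA = functional with mixed derivative sign
    }
    if (functional) {
      row <- ctx_grid[r, , drop = FALSE]
      row$.sign <- if (anyNA(arc_signs)) NA_integer_ else
        as.integer(prod(arc_signs))
      res[[length(res) + 1L]] <- row
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    o <- ctx_grid[0, , drop = FALSE]
    o$.sign <- integer()
    o
  }
  rownames(out) <- NULL
  attr(out, "externals") <- ext
  out
}

# derivative sign of f_v w.r.t. u under context K: +1 / -1 when all nonzero
# local derivatives share a sign, NA when mixed, 0 when never nonzero
.arc_derivative_sign <- function(model, u, v, K, regs_v, maxlev) {
  others <- setdiff(regs_v, c(u, names(K)))
  grid <- if (length(others))
    do.call(expand.grid, c(lapply(others, function(o) 0:maxlev[[o]]),
                           KEEP.OUT.ATTRS = FALSE))
  else data.frame(row.names = 1L)
  if (length(others)) names(grid) <- others
  seen <- integer()
  base <- stats::setNames(rep(0L, nrow(model$components)),
                          model$components$name)
  base[names(K)] <- K
  for (r in seq_len(nrow(grid))) {
    s <- base
    if (length(others)) s[others] <- as.integer(grid[r, ])
    for (t in seq_len(maxlev[[u]])) {
      s[u] <- t
      hi <- .resolve_level(model, v, s)
      s[u] <- t - 1L
      lo <- .resolve_level(model, v, s)
      d <- sign(hi - lo)
      if (d != 0L) seen <- union(seen, d)
    }
  }
  if (!length(seen)) 0L
  else if (length(seen) == 1L) seen
  else NA_integer_
}

# raw resolved level without input / totality guards (internal)
.resolve_level <- function(model, component, state, cutoff = 3L) {
  ci <- match(component, model$components$name)
  terms <- .terms_for(model, component, cutoff)
  if (!length(terms)) return(model$components$default_level[ci])
  sat <- vapply(terms, function(t) isTRUE(.term_status(t, state)), logical(1))
  if (!any(sat)) return(model$components$default_level[ci])
  max(vapply(terms[sat], function(t) t$target_level, integer(1)))
}

#' Is a feedback loop functional?
#' @param model A \code{lddr_model}.
#' @param loop A loop record.
#' @return \code{TRUE} when at least one functionality context exists.
#' @export
is_functional <- function(model, loop)
  nrow(functionality_context(model, loop)) > 0L
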