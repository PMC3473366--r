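# Independent brute-force oracles. Each recomputes a quantity by exhaustive
# enumeration, sharing no code path with the implementation it checks.

# resolved level computed directly from the definition
oracle_resolve <- function(model, component, state, cutoff = 3L) {
  default <- model$components$default_level[
    match(component, model$components$name)]
  best <- NULL
  for (t in model$terms) {
    if (t$target != component || t$time_scale > cutoff) next
    l <- t$literals
    sat <- TRUE
    if (nrow(l))
      for (r in seq_len(nrow(l))) {
        s <- (state[[l$component[r]]] >= l$threshold[r])
        if (l$negated[r]) s <- !s
        if (!s) { sat <- FALSE; break }
      }
    if (sat) best <- max(best, t$target_level)
  }
  if (is.null(best)) default else best
}

# forced-value fixpoint by GLOBAL enumeration: a component becomes
# determined when all completions of the whole current partial state agree
oracle_lss <- function(model, clamps = NULL, cutoff = 3L) {
  comp <- model$components
  state <- setNames(rep(NA_integer_, nrow(comp)), comp$name)
  if (length(clamps)) state[names(clamps)] <- as.integer(clamps)
  free_inputs <- comp$name[comp$is_input & !(comp$name %in% names(clamps))]
  state[free_inputs] <- comp$default_level[match(free_inputs, comp$name)]
  todo <- comp$name[!comp$is_input & !(comp$name %in% names(clamps))]
  completions <- function(state) {
    und <- names(state)[is.na(state)]
    if (!length(und)) return(list(state))
    grid <- do.call(expand.grid, c(lapply(und, function(u)
      0:comp$max_level[match(u, comp$name)]), KEEP.OUT.ATTRS = FALSE))
    names(grid) <- und
    lapply(seq_len(nrow(grid)), function(r) {
      s <- state; s[und] <- as.integer(grid[r, ]); s
    })
  }
  repeat {
    changed <- FALSE
    comps_list <- completions(state)
    for (cn in todo) {
      if (!is.na(state[[cn]])) next
      vals <- unique(vapply(comps_list, function(s)
        oracle_resolve(model, cn, s, cutoff), integer(1)))
      if (length(vals) == 1L) {
        state[[cn]] <- vals
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  state
}

# parity reachability via DFS over all walks up to length 2n with memo
oracle_signed_reachability <- function(graph) {
  nodes <- graph_nodes(graph)
  n <- length(nodes)
  pos <- neg <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (!nrow(graph)) return(list(positive = pos, negative = neg))
  for (i in seq_len(n)) {
    # walk states: (node, parity); visit each at most once => fixpoint
    seen <- matrix(FALSE, n, 2L)
    stack <- list()
    for (k in which(graph$source == nodes[i])) {
      j <- match(graph$target[k], nodes)
      p <- if (graph$sign[k] > 0) 1L else 2L
      if (!seen[j, p]) { seen[j, p] <- TRUE; stack[[length(stack) + 1L]] <- c(j, p) }
    }
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in which(graph$source == nodes[cur[1L]])) {
        j <- match(graph$target[k], nodes)
        p <- if ((graph$sign[k] > 0) == (cur[2L] == 1L)) 1L else 2L
        if (!seen[j, p]) { seen[j, p] <- TRUE; stack[[length(stack) + 1L]] <- c(j, p) }
      }
    }
    pos[i, ] <- seen[, 1L]
    neg[i, ] <- seen[, 2L]
  }
  list(positive = pos, negative = neg)
}

# all simple cycles by exhaustive path extension from every node
oracle_simple_cycles <- function(graph, max_length = 8L) {
  nodes <- graph_nodes(graph)
  found <- list()
  arcs <- as.data.frame(graph)
  extend <- function(path, signs) {
    last <- path[length(path)]
    rows <- which(arcs$source == last)
    for (k in rows) {
      nxt <- arcs$target[k]
      s <- arcs$sign[k]
      if (nxt == path[1L]) {
        # canonical: path must start at its smallest node
        if (path[1L] == min(path))
          for (acc in signs)
            found[[length(found) + 1L]] <<-
              list(nodes = path, sign = as.integer(acc * s))
      } else if (!(nxt %in% path) && length(path) < max_length) {
        extend(c(path, nxt), unique(signs * s))
      }
    }
  }
  for (v in nodes) extend(v, 1L)
  key <- vapply(found, function(l) paste(c(l$nodes, l$sign), collapse = "|"),
                character(1))
  found[!duplicated(key)]
}

# dependency matrix from exhaustive simple-path enumeration: breadth-first
# extension of arc lists, closing cycles for negative-loop membership
oracle_dependency_matrix <- function(graph) {
  nodes <- graph_nodes(graph)
  n <- length(nodes)
  pos <- neg <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  on_neg <- setNames(rep(FALSE, n), nodes)
  arcs <- as.data.frame(graph)
  frontier <- lapply(seq_len(nrow(arcs)), function(k)
    list(nodes = c(arcs$source[k], arcs$target[k]), sign = arcs$sign[k]))
  while (length(frontier)) {
    p <- frontier[[length(frontier)]]
    frontier[[length(frontier)]] <- NULL
    a <- p$nodes[1L]; b <- p$nodes[length(p$nodes)]
    closed <- a == b && length(p$nodes) > 1L
    if (closed) {
      if (p$sign > 0) pos[a, a] <- TRUE else neg[a, a] <- TRUE
      if (p$sign < 0) on_neg[unique(p$nodes)] <- TRUE
      next  # closed paths are not extended
    }
    if (p$sign > 0) pos[a, b] <- TRUE else neg[a, b] <- TRUE
    for (k in which(arcs$source == b)) {
      tgt <- arcs$target[k]
      if (tgt == a || !(tgt %in% p$nodes))
        frontier[[length(frontier) + 1L]] <-
          list(nodes = c(p$nodes, tgt), sign = p$sign * arcs$sign[k])
    }
  }
  reach <- pos | neg
  m <- matrix("NO_EFFECT", n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!pos[i, j] && !neg[i, j]) next
    if (pos[i, j] && neg[i, j]) { m[i, j] <- "AMBIVALENT"; next }
    onpath <- union(which(reach[i, ] & reach[, j]), c(i, j))
    weak <- any(on_neg[onpath])
    m[i, j] <- if (pos[i, j]) {
      if (weak) "WEAK_ACTIVATOR" else "STRONG_ACTIVATOR"
    } else {
      if (weak) "WEAK_INHIBITOR" else "STRONG_INHIBITOR"
    }
  }
  m
}

# exhaustive subset-minimal intervention search
oracle_mis <- function(model, scenario_clamps, goal, max_cardinality,
                       candidates, cutoff = 2L) {
  candidates <- candidates[!(candidates$component %in%
                               names(scenario_clamps)), , drop = FALSE]
  nc <- nrow(candidates)
  base <- logical_steady_state(model, scenario_clamps, cutoff)
  if (goal_holds(base, goal)) return(list())
  sat <- list()
  for (size in seq_len(min(max_cardinality, nc))) {
    for (idx in utils::combn(nc, size, simplify = FALSE)) {
      comps <- candidates$component[idx]
      if (anyDuplicated(comps)) next
      iv <- setNames(as.integer(candidates$level[idx]), comps)
      lss <- logical_steady_state(model, c(scenario_clamps, iv), cutoff)
      if (goal_holds(lss, goal)) sat[[length(sat) + 1L]] <- iv
    }
  }
  # filter to subset-minimal
  minimal <- Filter(function(iv) {
    !any(vapply(sat, function(o)
      length(o) < length(iv) && all(names(o) %in% names(iv)) &&
        all(iv[names(o)] == o), logical(1)))
  }, sat)
  minimal
}

# truth-table agreement of a model and its reduction (removed set resolved)
oracle_truth_tables_agree <- function(original, reduced) {
  removed <- setdiff(original$components$name, reduced$components$name)
  for (s2 in enumerate_states(reduced)) {
    s1 <- setNames(rep(NA_integer_, nrow(original$components)),
                   original$components$name)
    s1[names(s2)] <- s2
    # resolve removed components in dependency order (no cycles among them)
    repeat {
      filled <- FALSE
      for (rn in removed) {
        if (!is.na(s1[[rn]])) next
        regs <- unique(unlist(lapply(original$terms, function(t)
          if (t$target == rn) t$literals$component)))
        if (anyNA(s1[regs])) next
        s1[[rn]] <- oracle_resolve(original, rn, s1)
        filled <- TRUE
      }
      if (!anyNA(s1) || !filled) break
    }
    if (anyNA(s1)) stop("could not resolve removed components (cyclic?)")
    for (cn in reduced$components$name[!reduced$components$is_input]) {
      if (oracle_resolve(reduced, cn, s2) != oracle_resolve(original, cn, s1))
        return(FALSE)
    }
  }
  TRUE
}

# functionality of a loop by full state-space discrete-derivative testing:
# for an external-regulator assignment K, every loop arc u -> v must have a
# state consistent with K where stepping u across a threshold changes f_v
oracle_functional_contexts <- function(model, loop) {
  nodes <- loop$nodes
  comp <- model$components
  regs_of <- lapply(setNames(nodes, nodes), function(v)
    unique(unlist(lapply(model$terms, function(t)
      if (t$target == v) t$literals$component))))
  ext <- sort(setdiff(unique(unlist(regs_of)), nodes))
  states <- enumerate_states(model)
  arcs <- cbind(nodes, c(nodes[-1L], nodes[1L]))
  ctx_grid <- if (length(ext))
    do.call(expand.grid, c(lapply(ext, function(e)
      0:comp$max_level[match(e, comp$name)]), KEEP.OUT.ATTRS = FALSE))
  else data.frame(row.names = 1L)
  if (length(ext)) names(ctx_grid) <- ext
  res <- list()
  for (r in seq_len(nrow(ctx_grid))) {
    K <- if (length(ext)) setNames(as.integer(ctx_grid[r, ]), ext) else integer()
    ok <- TRUE
    for (a in seq_len(nrow(arcs))) {
      u <- arcs[a, 1L]; v <- arcs[a, 2L]
      func <- FALSE
      for (s in states) {
        if (length(K) && !all(s[names(K)] == K)) next
        if (s[[u]] == 0L) next
        s_lo <- s; s_lo[[u]] <- s[[u]] - 1L
        if (oracle_resolve(model, v, s) != oracle_resolve(model, v, s_lo)) {
          func <- TRUE; break
        }
      }
      if (!func) { ok <- FALSE; break }
    }
    if (ok) res[[length(res) + 1L]] <- K
  }
  res
}
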