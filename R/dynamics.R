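# Asynchronous dynamics under ranked priority classes: successors,
# state-transition graphs, attractor detection, symbolic fixed points.

#' Priority scheme over (component, direction) transitions
#'
#' Each class is a set of (component, direction) pairs sharing a rank; rank 1
#' is the highest priority. At any state, among all concurrent candidate
#' transitions only those of the highest-ranked class fire, asynchronously
#' within the class. Pairs not listed in any class get the lowest rank.
#'
#' @param ... Classes in rank order; each a \code{data.frame} with columns
#'   \code{component} and \code{direction} (\code{"INCREASE"} /
#'   \code{"DECREASE"}), or a character vector \code{"comp:INCREASE"}.
#' @return An object of class \code{lddr_scheme}.
#' @export
priority_scheme <- function(...) {
  classes <- lapply(list(...), function(cl) {
    if (is.character(cl)) {
      parts <- strsplit(cl, ":", fixed = TRUE)
      cl <- data.frame(component = vapply(parts, `[`, "", 1L),
                       direction = vapply(parts, `[`, "", 2L),
                       stringsAsFactors = FALSE)
    }
    stopifnot(all(cl$direction %in% c("INCREASE", "DECREASE")))
    cl
  })
  keys <- unlist(lapply(classes, function(cl)
    paste(cl$component, cl$direction)))
  if (anyDuplicated(keys))
    stop("a (component, direction) pair appears in two priority classes",
         call. = FALSE)
  structure(list(classes = classes), class = "lddr_scheme")
}

#' Flat (single-class) priority scheme
#'
#' Plain asynchronous updating: every candidate transition fires.
#' @export
flat_scheme <- function() priority_scheme()

.rank_of <- function(scheme, component, direction) {
  for (i in seq_along(scheme$classes)) {
    cl <- scheme$classes[[i]]
    if (any(cl$component == component & cl$direction == direction))
      return(i)
  }
  length(scheme$classes) + 1L
}

#' Asynchronous successors of a state under a priority scheme
#'
#' For each non-input component the current level is compared with its
#' resolved target level; a candidate transition moves one step (+1 or -1)
#' toward the target. Candidates are filtered to the highest-priority
#' (minimal rank) class present; each surviving candidate yields one
#' successor. The empty set marks a logical steady state.
#'
#' @param model A \code{lddr_model}.
#' @param state Total named state vector.
#' @param scheme An \code{lddr_scheme} (default [flat_scheme()]).
#' @param cutoff Time-scale cutoff for term evaluation (default 3).
#' @return List of successor states (possibly empty).
#' @export
successors <- function(model, state, scheme = flat_scheme(), cutoff = 3L) {
  comp <- model$components
  cand <- list()
  for (i in which(!comp$is_input)) {
    cn <- comp$name[i]
    tgt <- .resolve_level(model, cn, state, cutoff)
    cur <- state[[cn]]
    if (tgt == cur) next
    dir <- if (tgt > cur) "INCREASE" else "DECREASE"
    cand[[length(cand) + 1L]] <- list(
      component = cn, step = if (tgt > cur) 1L else -1L,
      rank = .rank_of(scheme, cn, dir))
  }
  if (!length(cand)) return(list())
  ranks <- vapply(cand, function(c0) c0$rank, integer(1))
  cand <- cand[ranks == min(ranks)]
  lapply(cand, function(c0) {
    s <- state
    s[[c0$component]] <- s[[c0$component]] + c0$step
    s
  })
}

#' Build the reachable state-transition graph
#'
#' Breadth-first closure of [successors()] from the initial states. Node
#' labels are digit strings in the declared component order.
#'
#' @param model A \code{lddr_model}.
#' @param initial A state or list of states (see [network_state()]).
#' @param scheme An \code{lddr_scheme}.
#' @param cutoff Time-scale cutoff (default 3).
#' @param max_states State-space guard (default 1e6); exceeding it is an
#'   explicit overflow error.
#' @return An object of class \code{lddr_stg}: list with \code{states}
#'   (named list label -> state vector), \code{transitions}
#'   (\code{data.frame} from, to), \code{initial} (labels).
#' @export
build_stg <- function(model, initial, scheme = flat_scheme(), cutoff = 3L,
                      max_states = 1e6) {
  if (!is.list(initial)) initial <- list(initial)
  stopifnot(length(initial) >= 1L)
  states <- list()
  from <- character(); to <- character()
  queue <- initial
  init_labels <- vapply(initial, state_label, character(1))
  while (length(queue)) {
    s <- queue[[1L]]; queue[[1L]] <- NULL
    lab <- state_label(s)
    if (!is.null(states[[lab]])) next
    states[[lab]] <- s
    if (length(states) > max_states)
      stop(sprintf("state transition graph exceeds %g states", max_states),
           call. = FALSE)
    succ <- successors(model, s, scheme, cutoff)
    for (s2 in succ) {
      lab2 <- state_label(s2)
      from <- c(from, lab); to <- c(to, lab2)
      if (is.null(states[[lab2]])) queue[[length(queue) + 1L]] <- s2
    }
  }
  structure(list(states = states,
                 transitions = data.frame(from = from, to = to,
                                          stringsAsFactors = FALSE),
                 initial = unique(init_labels)),
            class = "lddr_stg")
}

#' @export
print.lddr_stg <- function(x, ...) {
  cat(sprintf("State transition graph: %d states, %d transitions (%d initial)\n",
              length(x$states), nrow(x$transitions), length(x$initial)))
  invisible(x)
}

#' Attractors of a state-transition graph
#'
#' Attractors are the terminal strongly connected components: a
#' \code{STEADY_STATE} is a singleton without outgoing transitions, a
#' \code{SIMPLE_LOOP} a cycle in which every member has exactly one
#' successor, a \code{COMPLEX_LOOP} a terminal SCC with branching
#' (overlapping cycles). Every state of a finite STG reaches at least one
#' attractor.
#'
#' @param stg An \code{lddr_stg}.
#' @return List of attractors: \code{list(states = <labels>, kind =)}.
#' @export
find_attractors <- function(stg) {
  labs <- names(stg$states)
  g <- igraph::graph_from_data_frame(stg$transitions, directed = TRUE,
                                     vertices = labs)
  sc <- igraph::components(g, mode = "strong")
  memb <- sc$membership
  out <- list()
  el <- stg$transitions
  succ_of <- split(el$to, el$from)
  for (k in seq_len(sc$no)) {
    members <- labs[memb == k]
    succ_all <- unique(unlist(succ_of[members]))
    if (length(setdiff(succ_all, members))) next  # not terminal
    kind <- if (length(members) == 1L && !length(succ_all)) "STEADY_STATE"
    else {
      nsucc <- vapply(members, function(m) length(unique(succ_of[[m]])),
                      integer(1))
      if (all(nsucc == 1L)) "SIMPLE_LOOP" else "COMPLEX_LOOP"
    }
    out[[length(out) + 1L]] <- list(states = sort(members), kind = kind)
  }
  out[order(vapply(out, function(a) a$states[1L], character(1)))]
}

#' All total fixed points, without building a state-transition graph
#'
#' Backtracking constraint search over component levels: a total state is a
#' fixed point when every non-input component already sits at its resolved
#' target level. Fixed points are independent of the updating scheme, so
#' their presence or absence decides between steady-state and cyclic
#' attractors even for models whose state space is too big to enumerate
#' dynamically.
#'
#' Clamped components are held at their clamp; inputs not clamped are held at
#' their default level.
#'
#' @param model A \code{lddr_model}.
#' @param clamps Named integer vector of fixed levels.
#' @param cutoff Time-scale cutoff (default 3).
#' @return List of fixed-point states (named integer vectors).
#' @export
steady_states_symbolic <- function(model, clamps = NULL, cutoff = 3L) {
  model <- apply_clamps(model, clamps)
  comp <- model$components
  n <- nrow(comp)
  maxlev <- stats::setNames(comp$max_level, comp$name)

  # order free components by distance from the inputs so constraints bind early
  graph <- interaction_graph(model, cutoff)
  dist <- stats::setNames(rep(Inf, n), comp$name)
  dist[comp$name[comp$is_input]] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(graph))) {
      d <- dist[[graph$source[k]]] + 1
      if (d < dist[[graph$target[k]]]) {
        dist[[graph$target[k]]] <- d
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  free <- comp$name[!comp$is_input]
  free <- free[order(dist[free], free)]
  regs_of <- lapply(stats::setNames(free, free), function(cn)
    unique(unlist(lapply(.terms_for(model, cn, cutoff), function(t)
      t$literals$component))))

  state <- stats::setNames(rep(NA_integer_, n), comp$name)
  state[comp$name[comp$is_input]] <-
    comp$default_level[comp$is_input]
  found <- list()
  consistent <- function(state, assigned) {
    # check every assigned free component whose regulators are all assigned
    for (cn in assigned) {
      if (anyNA(state[regs_of[[cn]]])) next
      if (.resolve_level(model, cn, state, cutoff) != state[[cn]])
        return(FALSE)
    }
    TRUE
  }
  recurse <- function(state, idx, assigned) {
    if (idx > length(free)) {
      found[[length(found) + 1L]] <<- state[comp$name]
      return(invisible())
    }
    cn <- free[idx]
    for (v in 0:maxlev[[cn]]) {
      state[[cn]] <- v
      if (consistent(state, c(assigned, cn)))
        recurse(state, idx + 1L, c(assigned, cn))
    }
  }
  recurse(state, 1L, character())
  found
}
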