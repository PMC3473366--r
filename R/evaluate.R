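# Target-level evaluation and clamping.

.terms_for <- function(model, component, cutoff = 3L) {
  Filter(function(t) t$target == component && t$time_scale <= cutoff,
         model$terms)
}

.literal_status <- function(lits, state) {
  # TRUE / FALSE / NA (undetermined) per literal under a (partial) state
  if (!nrow(lits)) return(logical(0))
  lev <- state[lits$component]
  (lev >= lits$threshold) != lits$negated
}

.term_status <- function(term, state) {
  st <- .literal_status(term$literals, state)
  if (any(!st, na.rm = TRUE)) return(FALSE)
  if (anyNA(st)) return(NA)
  TRUE
}

#' Resolved target level of a component in a total state
#'
#' Terms of the component with \code{time_scale <= cutoff} are evaluated; the
#' resolved level is the maximum \code{target_level} over satisfied terms, or
#' the component's default (basal) level when no term is satisfied. Explicit
#' inactivating terms (\code{target_level} 0, e.g. degradation) are expected to
#' be encoded so that they are the only term satisfiable in their context (see
#' [find_term_conflicts()]); the IkBa cascade 2 -> 1 -> 0 under rising IKK
#' activity is the canonical example.
#'
#' @param model A \code{lddr_model}.
#' @param component A non-input component name.
#' @param state Total named state vector (see [network_state()]).
#' @param cutoff Time-scale cutoff in \code{1:3} (cumulative; default 3).
#' @return Integer level.
#' @export
evaluate_target_level <- function(model, component, state, cutoff = 3L) {
  component <- resolve_component(model, component)
  ci <- match(component, model$components$name)
  if (model$components$is_input[ci])
    stop(sprintf("'%s' is an input; inputs have no logical function", component),
         call. = FALSE)
  if (anyNA(state[model$components$name]))
    stop("state must be total (every component assigned)", call. = FALSE)
  terms <- .terms_for(model, component, cutoff)
  sat <- vapply(terms, function(t) isTRUE(.term_status(t, state)), logical(1))
  if (!any(sat)) return(model$components$default_level[ci])
  max(vapply(terms[sat], function(t) t$target_level, integer(1)))
}

#' Flag states where inactivating and activating terms fire together
#'
#' The maximum-resolving rule assumes curated, conflict-free functions: a
#' satisfied \code{target_level}-0 term should never fire together with a
#' higher-level term for the same target. This validator enumerates (or
#' samples) total states and reports violations.
#'
#' @param model A \code{lddr_model}.
#' @param states Optional list of states to check; by default all total states
#'   when the state space has at most \code{limit} states, else an error.
#' @param limit State-space cap for exhaustive checking (default 4096).
#' @return \code{data.frame} with columns state (label), component, levels
#'   (fired target levels); zero rows when consistent.
#' @export
find_term_conflicts <- function(model, states = NULL, limit = 4096L) {
  if (is.null(states)) {
    sz <- prod(model$components$max_level + 1)
    if (sz > limit)
      stop(sprintf("state space too large (%g states); pass explicit states", sz),
           call. = FALSE)
    states <- enumerate_states(model)
  }
  out <- list()
  for (s in states) {
    for (cn in model$components$name[!model$components$is_input]) {
      terms <- .terms_for(model, cn)
      sat <- vapply(terms, function(t) isTRUE(.term_status(t, s)), logical(1))
      levs <- vapply(terms[sat], function(t) t$target_level, integer(1))
      if (length(levs) && any(levs == 0L) && any(levs > 0L))
        out[[length(out) + 1L]] <- data.frame(
          state = state_label(s), component = cn,
          levels = paste(sort(unique(levs)), collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(state = character(), component = character(),
                      levels = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Enumerate all total states of a model
#'
#' @param model A \code{lddr_model}.
#' @param fixed Named integer vector of components held fixed.
#' @return List of named state vectors (declared component order).
#' @export
enumerate_states <- function(model, fixed = NULL) {
  comp <- model$components
  ranges <- lapply(seq_len(nrow(comp)), function(i) {
    nm <- comp$name[i]
    if (!is.null(fixed) && nm %in% names(fixed)) as.integer(fixed[[nm]])
    else 0:comp$max_level[i]
  })
  grid <- do.call(expand.grid, c(ranges, KEEP.OUT.ATTRS = FALSE))
  names(grid) <- comp$name
  lapply(seq_len(nrow(grid)), function(r)
    stats::setNames(as.integer(grid[r, ]), comp$name))
}

#' Fix components at given levels ("clamping")
#'
#' Returns a model in which each clamped component loses its incoming terms
#' and becomes an input with the clamp as its default level: loss of function
#' is a clamp at 0, constitutive activity a clamp at the maximum (or stated)
#' level. Used to encode mutations and sustained stimuli.
#'
#' @param model A \code{lddr_model}.
#' @param clamps Named integer vector, component -> fixed level.
#' @return A \code{lddr_model}.
#' @export
apply_clamps <- function(model, clamps) {
  if (is.null(clamps) || !length(clamps)) return(model)
  nm <- vapply(names(clamps), function(n) resolve_component(model, n),
               character(1))
  lv <- as.integer(clamps)
  for (i in seq_along(nm)) {
    ci <- match(nm[i], model$components$name)
    ml <- model$components$max_level[ci]
    if (lv[i] < 0L || lv[i] > ml)
      stop(sprintf("clamp %d out of range for %s (max %d)", lv[i], nm[i], ml),
           call. = FALSE)
    model$components$default_level[ci] <- lv[i]
  }
  model$terms <- Filter(function(t) !(t$target %in% nm), model$terms)
  targets <- vapply(model$terms, function(t) t$target, character(1))
  model$components$is_input <- !(model$components$name %in% targets)
  model
}
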