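# Three-valued logical steady states and pathway (active-term) reports.

#' Logical steady state under clamps and a time-scale cutoff
#'
#' Restricts the model to terms with \code{time_scale <= cutoff} (time scales
#' are cumulative: the cutoff-2 model contains scale-1 and scale-2
#' interactions, the late feedback layer is scale 3) and computes the unique
#' maximal set of forced activity levels as a three-valued fixpoint: a
#' non-clamped component becomes determined exactly when every completion of
#' the current partial state yields the same resolved target level, which a
#' local enumeration over the component's undetermined regulators decides
#' exactly. Components in unresolved feedback (e.g. negative cycles without
#' clamps) stay \code{NA} (undetermined) — this is the signature by which a
#' cyclic attractor is inferred. The fixpoint is independent of the component
#' visitation order and of any updating scheme.
#'
#' Clamped components are determined at their clamp; inputs not clamped sit at
#' their default level.
#'
#' @param model A \code{lddr_model}.
#' @param clamps Named integer vector of fixed levels (mutations, stimuli).
#' @param timescale_cutoff Cutoff in \code{1:3} (default 3).
#' @return Named integer vector over all components with \code{NA} for
#'   undetermined levels (class \code{lddr_lss}).
#' @export
logical_steady_state <- function(model, clamps = NULL, timescale_cutoff = 3L) {
  stopifnot(timescale_cutoff %in% 1:3)
  comp <- model$components
  state <- stats::setNames(rep(NA_integer_, nrow(comp)), comp$name)
  if (!is.null(clamps) && length(clamps)) {
    nm <- vapply(names(clamps), function(n) resolve_component(model, n),
                 character(1))
    lv <- as.integer(clamps)
    for (i in seq_along(nm)) {
      ml <- comp$max_level[match(nm[i], comp$name)]
      if (lv[i] < 0L || lv[i] > ml)
        stop(sprintf("clamp %d out of range for %s (max %d)", lv[i], nm[i], ml),
             call. = FALSE)
    }
    state[nm] <- lv
  } else nm <- character()
  free_inputs <- comp$name[comp$is_input & !(comp$name %in% nm)]
  state[free_inputs] <- comp$default_level[match(free_inputs, comp$name)]

  # per-component cached structure under the cutoff
  todo <- comp$name[!(comp$name %in% nm) & !comp$is_input]
  terms_of <- lapply(stats::setNames(todo, todo), function(cn)
    .terms_for(model, cn, timescale_cutoff))
  regs_of <- lapply(terms_of, function(ts)
    unique(unlist(lapply(ts, function(t) t$literals$component))))
  maxlev <- stats::setNames(comp$max_level, comp$name)
  defaults <- stats::setNames(comp$default_level, comp$name)

  repeat {
    changed <- FALSE
    for (cn in todo) {
      if (!is.na(state[[cn]])) next
      v <- .forced_level(terms_of[[cn]], regs_of[[cn]], state, maxlev,
                         defaults[[cn]])
      if (!is.na(v)) {
        state[[cn]] <- v
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(state, class = c("lddr_lss", class(state)))
}

# forced level of one component: identical resolved level over all completions
# of its undetermined regulators, else NA
.forced_level <- function(terms, regs, state, maxlev, default,
                          completion_cap = 65536L) {
  und <- regs[is.na(state[regs])]
  resolve <- function(s) {
    sat <- vapply(terms, function(t) isTRUE(.term_status(t, s)), logical(1))
    if (!any(sat)) default
    else max(vapply(terms[sat], function(t) t$target_level, integer(1)))
  }
  if (!length(und)) return(resolve(state))
  sz <- prod(maxlev[und] + 1)
  if (sz > completion_cap) return(NA_integer_)  # leave undetermined
  grid <- do.call(expand.grid,
                  c(lapply(und, function(u) 0:maxlev[[u]]),
                    KEEP.OUT.ATTRS = FALSE))
  names(grid) <- und
  vals <- vapply(seq_len(nrow(grid)), function(r) {
    s <- state
    s[und] <- as.integer(grid[r, ])
    resolve(s)
  }, integer(1))
  if (length(unique(vals)) == 1L) vals[1L] else NA_integer_
}

#' @export
print.lddr_lss <- function(x, ...) {
  v <- ifelse(is.na(x), "?", as.character(unclass(x)))
  cat("Logical steady state (? = undetermined):\n")
  print(stats::setNames(v, names(x)), quote = FALSE)
  invisible(x)
}

#' Terms of a component active in a (partial) state
#'
#' A term is active when every one of its literals is determined and
#' satisfied; literals touching undetermined components make the term
#' conservatively inactive. The active-term count of an output is the
#' paper-style count of intact pathways feeding it (e.g. "one of two pathways
#' promoting Cdc25A degradation blocked").
#'
#' @param model A \code{lddr_model}.
#' @param state Partial state (from [logical_steady_state()]) or total state.
#' @param component Component name.
#' @param cutoff Time-scale cutoff (default 3).
#' @return Integer vector of active term ids.
#' @export
active_terms <- function(model, state, component, cutoff = 3L) {
  component <- resolve_component(model, component)
  terms <- .terms_for(model, component, cutoff)
  ids <- vapply(terms, function(t) t$id, integer(1))
  act <- vapply(terms, function(t) isTRUE(.term_status(t, state)), logical(1))
  ids[act]
}
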