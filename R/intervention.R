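# Minimal intervention sets: goal specifications, goal checking, and the
# bounded-cardinality subset-minimal search.

#' Declarative goal over a logical steady state
#'
#' \code{require} entries must be determined at exactly the stated level
#' (undetermined never satisfies a requirement); \code{require_any} is a list
#' of (component, level) alternatives of which at least one must hold
#' determined. The tumour-sensitization goal, for instance, requires the
#' cell-cycle-arrest output and anti-apoptotic NF-kB at 0 while keeping the
#' onset-of-apoptosis output determined at 1.
#'
#' @param require Named integer vector, component -> required level.
#' @param require_any Optional \code{data.frame} with columns component,
#'   level: at least one must hold.
#' @return An object of class \code{lddr_goal}.
#' @export
goal_spec <- function(require = NULL, require_any = NULL) {
  structure(list(require = require, require_any = require_any),
            class = "lddr_goal")
}

#' Check a goal under scenario clamps plus an intervention set
#'
#' Computes the logical steady state under the union of the scenario clamps
#' (stimuli, pre-existing mutations) and the intervention clamps, then
#' evaluates the goal. Naming one component in both with different levels is
#' an error.
#'
#' @param model A \code{lddr_model}.
#' @param scenario_clamps Named integer vector (may be \code{NULL}).
#' @param interventions Named integer vector (may be \code{NULL}).
#' @param goal An \code{lddr_goal}.
#' @param cutoff Time-scale cutoff (default 2: before feedback inhibition).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
check_goal <- function(model, scenario_clamps, interventions, goal,
                       cutoff = 2L) {
  sc <- scenario_clamps
  iv <- interventions
  shared <- intersect(names(sc), names(iv))
  if (length(shared)) {
    conflict <- shared[sc[shared] != iv[shared]]
    if (length(conflict))
      stop("conflicting clamps on: ", paste(conflict, collapse = ", "),
           call. = FALSE)
    sc <- sc[setdiff(names(sc), shared)]
  }
  clamps <- c(sc, iv)
  lss <- logical_steady_state(model, clamps, timescale_cutoff = cutoff)
  goal_holds(lss, goal)
}

#' Evaluate a goal against a (partial) steady state
#' @param lss A state from [logical_steady_state()].
#' @param goal An \code{lddr_goal}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
goal_holds <- function(lss, goal) {
  req <- goal$require
  if (!is.null(req) && length(req)) {
    v <- lss[names(req)]
    if (anyNA(v) || any(v != as.integer(req))) return(FALSE)
  }
  ra <- goal$require_any
  if (!is.null(ra) && nrow(ra)) {
    v <- lss[ra$component]
    if (!any(!is.na(v) & v == ra$level)) return(FALSE)
  }
  TRUE
}

#' Default intervention candidates
#'
#' Sensitization searches consider removals (clamp at 0) of non-input,
#' non-output components; carcinogenesis (failure-mode) searches additionally
#' consider constitutive activation at every attainable level.
#'
#' @param model A \code{lddr_model}.
#' @param mode \code{"removal"} or \code{"removal_activation"}.
#' @param excluded Component names to exclude (e.g. curated exclusion lists).
#' @return \code{data.frame} with columns component, level.
#' @export
intervention_candidates <- function(model,
                                    mode = c("removal", "removal_activation"),
                                    excluded = character()) {
  mode <- match.arg(mode)
  comp <- model$components
  pool <- comp$name[!comp$is_input & !(comp$name %in% model$outputs) &
                      !(comp$name %in% excluded)]
  rows <- lapply(pool, function(cn) {
    ml <- comp$max_level[match(cn, comp$name)]
    lv <- if (mode == "removal") 0L else 0:ml
    data.frame(component = cn, level = lv, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(component = character(), level = integer(),
               stringsAsFactors = FALSE)
  out[order(out$component, out$level), , drop = FALSE]
}

#' Enumerate minimal intervention sets
#'
#' All subset-minimal clamp sets of size at most \code{max_cardinality} over
#' the candidate clamps that satisfy the goal under the scenario. Supersets
#' of reported sets are pruned; the output is ordered by size, then
#' lexicographically. When the scenario alone already satisfies the goal
#' (e.g. an ATM-deficient background under double-strand breaks meeting the
#' sensitization goal) the empty set is the unique minimal set and the
#' result is an empty list: no targets.
#'
#' @param model A \code{lddr_model}.
#' @param scenario_clamps Named integer vector (stimuli and mutations).
#' @param goal An \code{lddr_goal}.
#' @param max_cardinality Maximum number of interventions (default 3).
#' @param candidates \code{data.frame(component, level)} of allowed clamps;
#'   defaults to removals of non-input, non-output components.
#' @param excluded Component names excluded from the default candidates.
#' @param cutoff Time-scale cutoff (default 2).
#' @return List of minimal intervention sets (named integer vectors of
#'   clamps), each with attribute \code{minimal = TRUE}.
#' @export
enumerate_mis <- function(model, scenario_clamps, goal, max_cardinality = 3L,
                          candidates = NULL, excluded = character(),
                          cutoff = 2L) {
  stopifnot(max_cardinality >= 1L)
  if (is.null(candidates))
    candidates <- intervention_candidates(model, "removal", excluded)
  candidates <- candidates[order(candidates$component, candidates$level), ,
                           drop = FALSE]
  # drop candidates clashing with scenario clamps on the same component
  candidates <- candidates[!(candidates$component %in%
                               names(scenario_clamps)), , drop = FALSE]
  nc <- nrow(candidates)
  # the empty set is part of the subset order: when the scenario alone
  # already satisfies the goal, no nonempty set is minimal ("no targets")
  if (check_goal(model, scenario_clamps, NULL, goal, cutoff))
    return(list())
  found <- list()
  is_superset <- function(iv) {
    for (f in found) {
      if (all(names(f) %in% names(iv)) && all(iv[names(f)] == f))
        return(TRUE)
    }
    FALSE
  }
  for (size in seq_len(min(max_cardinality, nc))) {
    idx_sets <- utils::combn(nc, size, simplify = FALSE)
    for (idx in idx_sets) {
      comps <- candidates$component[idx]
      if (anyDuplicated(comps)) next
      iv <- stats::setNames(as.integer(candidates$level[idx]), comps)
      if (is_superset(iv)) next
      if (check_goal(model, scenario_clamps, iv, goal, cutoff))
        found[[length(found) + 1L]] <- structure(iv, minimal = TRUE)
    }
  }
  found
}

#' Format intervention sets in the tabular notation
#'
#' One row per set, clamps joined with \code{" & "}; removals print as the
#' bare component name, activations as \code{[level]component}.
#'
#' @param mis_list Result of [enumerate_mis()].
#' @param removals_bare Print level-0 clamps as bare names (default
#'   \code{TRUE}); otherwise every clamp prints as \code{[level]component}.
#' @return Character vector.
#' @export
format_mis <- function(mis_list, removals_bare = TRUE) {
  vapply(mis_list, function(iv) {
    parts <- vapply(seq_along(iv), function(i) {
      if (removals_bare && iv[i] == 0L) names(iv)[i]
      else sprintf("[%d]%s", iv[i], names(iv)[i])
    }, character(1))
    paste(parts, collapse = " & ")
  }, character(1))
}
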