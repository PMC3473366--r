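# Attractor-preserving reduction: removal of non-autoregulated components
# with substitution of their target-level functions into consuming terms.
#
# Conditions are manipulated as DNF objects: a list of conjuncts, each a
# literal data.frame (as in terms) with a "ts" attribute carrying the merged
# time-scale tag. TRUE is the single empty conjunct; FALSE the empty list.

.dnf_true <- function(ts = 1L)
  list(structure(literal("", TRUE, 1L)[0, ], ts = ts))
.dnf_false <- function() list()

# canonicalize one conjunct; NULL when contradictory, "TRUE" conjunct = 0 rows
.conj_simplify <- function(lits, maxlev) {
  ts <- attr(lits, "ts")
  if (!nrow(lits)) return(structure(lits, ts = ts))
  out <- list()
  for (cn in unique(lits$component)) {
    sub <- lits[lits$component == cn, , drop = FALSE]
    ml <- maxlev[[cn]]
    lo <- 0L  # level >= lo known
    hi <- ml  # level <= hi known
    for (r in seq_len(nrow(sub))) {
      if (sub$negated[r]) hi <- min(hi, sub$threshold[r] - 1L)
      else lo <- max(lo, sub$threshold[r])
    }
    if (lo > hi) return(NULL)  # contradiction
    if (lo > 0L) out[[length(out) + 1L]] <- literal(cn, FALSE, lo)
    if (hi < ml) out[[length(out) + 1L]] <- literal(cn, TRUE, hi + 1L)
  }
  res <- if (length(out)) do.call(rbind, out) else lits[0, , drop = FALSE]
  if (nrow(res) > 1L)
    res <- res[order(res$component, res$threshold, res$negated), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, ts = ts)
}

# does conjunct b imply conjunct a? (a's constraints all implied by b's)
.conj_implies <- function(b, a) {
  if (!nrow(a)) return(TRUE)
  if (!nrow(b)) return(FALSE)
  for (r in seq_len(nrow(a))) {
    cn <- a$component[r]
    if (a$negated[r]) {
      ok <- any(b$component == cn & b$negated & b$threshold <= a$threshold[r])
    } else {
      ok <- any(b$component == cn & !b$negated & b$threshold >= a$threshold[r])
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

.dnf_simplify <- function(dnf, maxlev) {
  dnf <- Filter(Negate(is.null),
                lapply(dnf, .conj_simplify, maxlev = maxlev))
  if (!length(dnf)) return(.dnf_false())
  # absorption: drop conjunct b when another conjunct a is implied by it
  keep <- rep(TRUE, length(dnf))
  for (i in seq_along(dnf)) {
    if (!keep[i]) next
    for (j in seq_along(dnf)) {
      if (i == j || !keep[j]) next
      if (.conj_implies(dnf[[j]], dnf[[i]])) {
        # ties (mutual implication): keep the first
        if (.conj_implies(dnf[[i]], dnf[[j]]) && i > j) next
        keep[j] <- FALSE
      }
    }
  }
  dnf[keep]
}

.dnf_or <- function(a, b, maxlev) .dnf_simplify(c(a, b), maxlev)

.dnf_and <- function(a, b, maxlev) {
  out <- list()
  for (ca in a) for (cb in b) {
    merged <- rbind(ca, cb)
    out[[length(out) + 1L]] <-
      structure(merged, ts = max(attr(ca, "ts"), attr(cb, "ts")))
  }
  .dnf_simplify(out, maxlev)
}

.dnf_not <- function(dnf, maxlev, ts) {
  if (!length(dnf)) return(.dnf_true(ts))
  acc <- .dnf_true(ts)
  for (conj in dnf) {
    if (!nrow(conj)) return(.dnf_false())
    neg <- lapply(seq_len(nrow(conj)), function(r)
      structure(literal(conj$component[r], !conj$negated[r],
                        conj$threshold[r]), ts = ts))
    acc <- .dnf_and(acc, neg, maxlev)
    if (!length(acc)) return(.dnf_false())
  }
  acc
}

# DNF condition for "resolved level of component >= t" (t >= 1)
.level_ge_dnf <- function(model, component, t, maxlev) {
  terms <- .terms_for(model, component)
  d <- model$components$default_level[match(component,
                                            model$components$name)]
  ts_all <- if (length(terms))
    max(vapply(terms, function(x) x$time_scale, integer(1))) else 1L
  sat_ge <- .dnf_false()
  for (tm in terms) {
    if (tm$target_level >= t)
      sat_ge <- .dnf_or(sat_ge, list(structure(tm$literals,
                                               ts = tm$time_scale)), maxlev)
  }
  if (d >= t) {
    none <- .dnf_true(ts_all)
    for (tm in terms)
      none <- .dnf_and(none, .dnf_not(list(structure(tm$literals,
                                                     ts = tm$time_scale)),
                                      maxlev, tm$time_scale), maxlev)
    sat_ge <- .dnf_or(sat_ge, none, maxlev)
  }
  sat_ge
}

.is_autoregulated <- function(model, component) {
  any(vapply(.terms_for(model, component), function(t)
    component %in% t$literals$component, logical(1)))
}

#' Remove one component, rewriting the logical functions
#'
#' The component's regulators are linked directly to its targets: every
#' literal \code{v >= t} over the removed component v is replaced by the
#' sum-of-products condition under which v's resolved level reaches t, and
#' the consuming terms are expanded back into sum-of-products form
#' (simplification by absorption and duplicate removal only). The resolved
#' level of every kept component, as a function of the kept components with v
#' resolved through its own function, is unchanged. The time-scale tag of a
#' merged term is the maximum of the merged tags (a path is as late as its
#' latest step).
#'
#' Autoregulated components are refused — a feedback loop reduces at most to
#' an autoregulation, and removing it would lose feedback loops and
#' attractors. Inputs and outputs are refused as well.
#'
#' @param model A \code{lddr_model}.
#' @param component Component to remove.
#' @return A \code{lddr_model} without the component.
#' @export
remove_component <- function(model, component) {
  component <- resolve_component(model, component)
  ci <- match(component, model$components$name)
  if (model$components$is_input[ci])
    stop(sprintf("'%s' is an input and cannot be removed", component),
         call. = FALSE)
  if (component %in% model$outputs)
    stop(sprintf("'%s' is an output and cannot be removed", component),
         call. = FALSE)
  if (.is_autoregulated(model, component))
    stop(sprintf(paste0("'%s' is autoregulated; removing it would lose ",
                        "feedback loops and attractors"), component),
         call. = FALSE)
  maxlev <- stats::setNames(model$components$max_level,
                            model$components$name)
  ml_v <- maxlev[[component]]
  ge_dnf <- lapply(seq_len(ml_v), function(t)
    .level_ge_dnf(model, component, t, maxlev))

  new_terms <- list()
  for (tm in model$terms) {
    if (tm$target == component) next
    l <- tm$literals
    uses <- nrow(l) > 0L && component %in% l$component
    if (!uses) {
      new_terms[[length(new_terms) + 1L]] <- tm
      next
    }
    keep_lits <- l[l$component != component, , drop = FALSE]
    dnf <- list(structure(keep_lits, ts = tm$time_scale))
    for (r in which(l$component == component)) {
      t0 <- l$threshold[r]
      cond <- ge_dnf[[t0]]
      if (l$negated[r])
        cond <- .dnf_not(cond, maxlev,
                         ts = max(vapply(cond, function(c0) attr(c0, "ts"),
                                         integer(1)), 1L))
      dnf <- .dnf_and(dnf, cond, maxlev)
    }
    for (conj in dnf) {
      new_terms[[length(new_terms) + 1L]] <-
        model_term(0L, tm$target, as.data.frame(conj),
                   tm$target_level,
                   max(tm$time_scale, attr(conj, "ts")))
    }
  }
  # dedupe identical terms (same target/level/literal set), renumber ids
  key <- vapply(new_terms, function(t) paste(
    t$target, t$target_level,
    paste(t$literals$component, t$literals$negated, t$literals$threshold,
          collapse = ";"), sep = "|"), character(1))
  new_terms <- new_terms[!duplicated(key)]
  ord <- order(vapply(new_terms, function(t) t$target, character(1)),
               key[!duplicated(key)])
  new_terms <- new_terms[ord]
  for (i in seq_along(new_terms)) new_terms[[i]]$id <- i
  logical_model(model$components[-ci, , drop = FALSE], new_terms,
                model$outputs, validate = FALSE)
}

#' Reduce a model to a kept component set, preserving attractors
#'
#' Iteratively removes every removable component outside \code{keep} in a
#' deterministic order (fewest regulators first, ties alphabetical),
#' recomputed each round. Inputs, outputs and autoregulated components are
#' never removed: all of them must be in \code{keep}, and a removal sequence
#' that strands an autoregulated component outside \code{keep} is refused
#' with the list of blockers. Fixed points of the result are exactly the
#' projections of the original model's fixed points, and the reduced model
#' has a fixed point iff the original does — the device by which cyclic
#' attractors of intractably large models are inferred.
#'
#' @param model A \code{lddr_model}.
#' @param keep Character vector of component names to keep.
#' @return The reduced \code{lddr_model}.
#' @export
reduce_to <- function(model, keep) {
  keep <- vapply(keep, function(n) resolve_component(model, n), character(1))
  repeat {
    comp <- model$components
    candidates <- setdiff(comp$name, keep)
    removable <- candidates[vapply(candidates, function(cn) {
      ci <- match(cn, comp$name)
      !comp$is_input[ci] && !(cn %in% model$outputs) &&
        !.is_autoregulated(model, cn)
    }, logical(1))]
    if (!length(removable)) {
      if (length(candidates)) {
        blockers <- vapply(candidates, function(cn) {
          ci <- match(cn, comp$name)
          if (comp$is_input[ci]) "input"
          else if (cn %in% model$outputs) "output"
          else "autoregulated"
        }, character(1))
        stop("cannot reduce further; blocked components outside keep: ",
             paste(sprintf("%s (%s)", candidates, blockers), collapse = ", "),
             call. = FALSE)
      }
      return(model)
    }
    n_regs <- vapply(removable, function(cn)
      length(unique(unlist(lapply(.terms_for(model, cn), function(t)
        t$literals$component)))), integer(1))
    pick <- removable[order(n_regs, removable)][1L]
    model <- remove_component(model, pick)
  }
}
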