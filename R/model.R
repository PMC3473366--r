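#' Construct a model component
#'
#' A component is a node of the logical network with a discrete activity level
#' in \code{0..max_level}. Most signalling species are Boolean
#' (\code{max_level = 1}); species whose low and high activities have distinct
#' substrate spectra (e.g. phosphorylated ATM, the IKK complex, IkBa) are
#' ternary (\code{max_level = 2}). The default level is the basal activity the
#' component holds when none of its terms is satisfied.
#'
#' @param name Component identifier (UTF-8, unique within a model).
#' @param max_level Maximum activity level, 1 or 2.
#' @param default_level Basal level in \code{0..max_level}.
#' @param annotation Free-text note (e.g. \code{"-P = phosphorylation"}).
#' @return A one-row \code{data.frame} usable in [logical_model()].
#' @export
model_component <- function(name, max_level = 1L, default_level = 0L,
                            annotation = "") {
  data.frame(name = as.character(name),
             max_level = as.integer(max_level),
             default_level = as.integer(default_level),
             annotation = as.character(annotation),
             stringsAsFactors = FALSE)
}

#' Construct a literal
#'
#' A literal tests one regulator: it is satisfied iff
#' \code{(level >= threshold) XOR negated}.
#'
#' @param component Regulator identifier.
#' @param negated Logical; \code{TRUE} for a NOT-literal.
#' @param threshold Activity threshold (>= 1).
#' @return A one-row \code{data.frame}.
#' @export
literal <- function(component, negated = FALSE, threshold = 1L) {
  data.frame(component = as.character(component),
             negated = as.logical(negated),
             threshold = as.integer(threshold),
             stringsAsFactors = FALSE)
}

#' Construct a term (hyperarc)
#'
#' A term is an AND-conjunction of literals pointing into one target; it is a
#' sufficient condition for the target to attain \code{target_level}. Terms
#' sharing a target are OR-connected alternatives. Each term carries a
#' time-scale tag 1 (early), 2 (intermediate) or 3 (late, feedback-initiating).
#'
#' An empty literal list denotes a constitutive term (always satisfied); such
#' terms arise from model reduction when a removed component's level condition
#' is a tautology.
#'
#' @param id Integer term id, unique within a model.
#' @param target Target component identifier.
#' @param literals \code{data.frame} of literals (rows from [literal()],
#'   \code{rbind}-ed), or \code{NULL} for a constitutive term.
#' @param target_level Level the target resolves to when the term fires.
#' @param time_scale Time-scale tag in \code{1:3}.
#' @return A term object (list).
#' @export
model_term <- function(id, target, literals, target_level = 1L,
                       time_scale = 1L) {
  if (is.null(literals)) {
    literals <- data.frame(component = character(), negated = logical(),
                           threshold = integer(), stringsAsFactors = FALSE)
  }
  list(id = as.integer(id), target = as.character(target),
       target_level = as.integer(target_level),
       time_scale = as.integer(time_scale),
       literals = literals)
}

#' Assemble a multi-valued logical model
#'
#' @param components \code{data.frame} of components ([model_component()] rows).
#' @param terms List of terms ([model_term()]).
#' @param outputs Character vector of output component names (phenotype read-outs
#'   such as cell cycle arrest or onset of apoptosis).
#' @param validate Run [validate_model()] (default \code{TRUE}).
#' @return An object of class \code{lddr_model}.
#' @export
logical_model <- function(components, terms = list(), outputs = character(),
                          validate = TRUE) {
  if (!is.data.frame(components)) components <- do.call(rbind, components)
  if (is.null(components$annotation)) components$annotation <- ""
  components$name <- as.character(components$name)
  rownames(components) <- NULL
  targets <- vapply(terms, function(t) t$target, character(1))
  components$is_input <- !(components$name %in% targets)
  m <- structure(list(components = components, terms = terms,
                      outputs = as.character(outputs)),
                 class = "lddr_model")
  if (validate) validate_model(m)
  m
}

#' @export
print.lddr_model <- function(x, ...) {
  nt <- length(x$terms)
  cat(sprintf("Multi-valued logical model: %d components, %d terms\n",
              nrow(x$components), nt))
  cat(sprintf("  inputs:  %s\n",
              paste(x$components$name[x$components$is_input], collapse = ", ")))
  if (length(x$outputs))
    cat(sprintf("  outputs: %s\n", paste(x$outputs, collapse = ", ")))
  tern <- x$components$name[x$components$max_level > 1L]
  if (length(tern))
    cat(sprintf("  ternary: %s\n", paste(tern, collapse = ", ")))
  invisible(x)
}

#' Validate a logical model
#'
#' Checks every structural invariant and reports all failures at once:
#' unique component names, levels within range, literal thresholds within the
#' referenced component's range, unique term ids, no duplicate literals within
#' a term, and every reference resolving to a declared component.
#'
#' @param model A \code{lddr_model}.
#' @return Invisibly \code{TRUE}; stops with the full failure list otherwise.
#' @export
validate_model <- function(model) {
  comp <- model$components
  errs <- character()
  add <- function(msg) errs[[length(errs) + 1L]] <<- msg
  if (anyDuplicated(comp$name))
    add(sprintf("duplicate component names: %s",
                paste(unique(comp$name[duplicated(comp$name)]), collapse = ", ")))
  if (!all(comp$max_level %in% 1:2))
    add("max_level must be 1 or 2 for every component")
  bad_def <- comp$default_level < 0L | comp$default_level > comp$max_level
  if (any(bad_def))
    add(sprintf("default_level out of range for: %s",
                paste(comp$name[bad_def], collapse = ", ")))
  maxlev <- stats::setNames(comp$max_level, comp$name)
  ids <- vapply(model$terms, function(t) t$id, integer(1))
  if (anyDuplicated(ids))
    add(sprintf("duplicate term ids: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (t in model$terms) {
    where <- sprintf("term %d (-> %s)", t$id, t$target)
    if (!t$target %in% comp$name) {
      add(sprintf("%s: unknown target", where))
      next
    }
    if (t$target_level < 0L || t$target_level > maxlev[[t$target]])
      add(sprintf("%s: target_level %d exceeds max_level %d",
                  where, t$target_level, maxlev[[t$target]]))
    if (!t$time_scale %in% 1:3)
      add(sprintf("%s: time_scale must be in 1..3", where))
    lits <- t$literals
    if (nrow(lits)) {
      key <- paste(lits$component, lits$negated, lits$threshold)
      if (anyDuplicated(key))
        add(sprintf("%s: duplicate literals", where))
      unknown <- setdiff(lits$component, comp$name)
      if (length(unknown))
        add(sprintf("%s: unknown literal component(s) %s",
                    where, paste(unknown, collapse = ", ")))
      known <- lits$component %in% comp$name
      over <- known & (lits$threshold > maxlev[lits$component] |
                         lits$threshold < 1L)
      over[is.na(over)] <- FALSE
      if (any(over))
        add(sprintf("%s: literal threshold out of range for %s",
                    where, paste(lits$component[over], collapse = ", ")))
    }
  }
  unknown_out <- setdiff(model$outputs, comp$name)
  if (length(unknown_out))
    add(sprintf("unknown output component(s): %s",
                paste(unknown_out, collapse = ", ")))
  if (length(errs))
    stop("model validation failed:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}

#' Canonicalize a model
#'
#' Sorts terms by id and literals by (component, threshold, negated), keeping
#' the declared component order (which fixes the digit order of state labels).
#'
#' @param model A \code{lddr_model}.
#' @return The canonicalized model.
#' @export
canonicalize_model <- function(model) {
  ids <- vapply(model$terms, function(t) t$id, integer(1))
  model$terms <- model$terms[order(ids)]
  model$terms <- lapply(model$terms, function(t) {
    l <- t$literals
    if (nrow(l) > 1L)
      t$literals <- l[order(l$component, l$threshold, l$negated), , drop = FALSE]
    rownames(t$literals) <- NULL
    t
  })
  model$outputs <- sort(model$outputs)
  model
}

#' Serialize a model to its native JSON document
#'
#' The native format has top-level keys \code{components} (name, max_level,
#' default_level, annotation), \code{terms} (id, target, target_level,
#' time_scale, literals) and \code{outputs}. [parse_model()] of the result is
#' the identity on canonical form.
#'
#' @param model A \code{lddr_model}.
#' @param path Optional file path; when given the document is written there.
#' @return The JSON document as a single string (invisibly when \code{path}
#'   is given).
#' @export
serialize_model <- function(model, path = NULL) {
  model <- canonicalize_model(model)
  comp <- model$components
  doc <- list(
    components = lapply(seq_len(nrow(comp)), function(i) list(
      name = comp$name[i], max_level = comp$max_level[i],
      default_level = comp$default_level[i],
      annotation = comp$annotation[i])),
    terms = lapply(model$terms, function(t) list(
      id = t$id, target = t$target, target_level = t$target_level,
      time_scale = t$time_scale,
      literals = lapply(seq_len(nrow(t$literals)), function(j) list(
        component = t$literals$component[j],
        negated = t$literals$negated[j],
        threshold = t$literals$threshold[j])))),
    outputs = as.list(model$outputs))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  json <- paste0(as.character(json), "\n")
  if (!is.null(path)) {
    writeLines(json, path, sep = "", useBytes = TRUE)
    return(invisible(json))
  }
  json
}

.get_field <- function(x, field, path, type = NULL) {
  if (is.null(x[[field]]))
    stop(sprintf("parse error at %s: missing field '%s'", path, field),
         call. = FALSE)
  x[[field]]
}

#' Parse a model from its native JSON document
#'
#' @param text JSON document (single string), or a file path to one.
#' @return A validated \code{lddr_model}.
#' @export
parse_model <- function(text) {
  if (length(text) == 1L && !grepl("[{]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop("parse error at $: not valid JSON: ",
                         conditionMessage(e), call. = FALSE))
  for (key in c("components", "terms"))
    if (is.null(doc[[key]]))
      stop(sprintf("parse error at $: missing field '%s'", key), call. = FALSE)
  comps <- do.call(rbind, lapply(seq_along(doc$components), function(i) {
    c0 <- doc$components[[i]]
    p <- sprintf("$.components[%d]", i)
    model_component(.get_field(c0, "name", p),
                    .get_field(c0, "max_level", p),
                    .get_field(c0, "default_level", p),
                    if (is.null(c0$annotation)) "" else c0$annotation)
  }))
  terms <- lapply(seq_along(doc$terms), function(i) {
    t0 <- doc$terms[[i]]
    p <- sprintf("$.terms[%d]", i)
    lits <- t0$literals
    litdf <- if (length(lits) == 0L) NULL else do.call(rbind, lapply(
      seq_along(lits), function(j) {
        l0 <- lits[[j]]
        pj <- sprintf("%s.literals[%d]", p, j)
        literal(.get_field(l0, "component", pj),
                if (is.null(l0$negated)) FALSE else l0$negated,
                if (is.null(l0$threshold)) 1L else l0$threshold)
      }))
    model_term(.get_field(t0, "id", p), .get_field(t0, "target", p), litdf,
               .get_field(t0, "target_level", p),
               if (is.null(t0$time_scale)) 1L else t0$time_scale)
  })
  outputs <- unlist(doc$outputs)
  if (is.null(outputs)) outputs <- character()
  logical_model(comps, terms, outputs)
}

#' Write a model to a file in the native JSON format
#' @param model A \code{lddr_model}.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  serialize_model(model, path = path)
  invisible(path)
}

#' Read a model from a native JSON file
#' @param path File path.
#' @export
read_model <- function(path) parse_model(path)

#' ASCII aliases of non-ASCII component names
#'
#' The literature mixes Greek and transliterated spellings of the NF-kB
#' pathway members; both resolve to the same component.
#'
#' @return Named character vector mapping ASCII alias -> canonical name.
#' @export
component_aliases <- function() {
  c("IkappaBalpha" = "IκBα",
    "IKKepsilon-P" = "IKKε-P",
    "IKKepsilon-S-P" = "IKKε-S-P",
    "NF-kappaB" = "NF-κB")
}

#' Resolve a component name against a model, honouring ASCII aliases
#' @param model A \code{lddr_model}.
#' @param name Component name or ASCII alias.
#' @return The canonical component name; errors when unknown.
#' @export
resolve_component <- function(model, name) {
  if (name %in% model$components$name) return(name)
  al <- component_aliases()
  if (name %in% names(al) && al[[name]] %in% model$components$name)
    return(al[[name]])
  rev_al <- stats::setNames(names(al), al)
  if (name %in% names(rev_al) && rev_al[[name]] %in% model$components$name)
    return(rev_al[[name]])
  stop(sprintf("unknown component '%s'", name), call. = FALSE)
}

#' Total network state
#'
#' @param model A \code{lddr_model}.
#' @param ... Named levels overriding the defaults, e.g. \code{DSBs_early = 1}.
#' @return Named integer vector over all components (declared order).
#' @export
network_state <- function(model, ...) {
  s <- stats::setNames(as.integer(model$components$default_level),
                       model$components$name)
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.numeric(ov[[1]]) &&
      !is.null(names(ov[[1]])))
    ov <- as.list(ov[[1]])
  for (nm in names(ov)) {
    cn <- resolve_component(model, nm)
    v <- as.integer(ov[[nm]])
    ml <- model$components$max_level[model$components$name == cn]
    if (v < 0L || v > ml)
      stop(sprintf("level %d out of range for %s (max %d)", v, cn, ml),
           call. = FALSE)
    s[[cn]] <- v
  }
  s
}

#' Digit-string label of a state (declared component order)
#' @param state Named integer state vector.
#' @return Single string, one digit per component.
#' @export
state_label <- function(state) paste(state, collapse = "")
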