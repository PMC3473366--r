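# Seeded generator of random multi-valued logical models with controlled
# structure (ternary fraction, density, signed-cycle content, planted motifs).

#' Configuration for the random-model generator
#'
#' Defaults emulate the structural class of curated signalling models:
#' mostly Boolean components with a minority of ternary ones, sparse
#' sum-of-products functions of one to three literals, occasional negation,
#' and time-scale tags concentrated on the early scales with a thinner late
#' (feedback) layer.
#'
#' @param n_components Number of components.
#' @param max_level_fraction Fraction of ternary (max level 2) components.
#' @param n_terms Number of terms (hyperarcs).
#' @param max_literals_per_term Maximum AND-width of a term.
#' @param negation_probability Probability a literal is negated.
#' @param forbid_negative_cycles Reject models containing a negative cycle.
#' @param forbid_positive_cycles Reject models containing a positive cycle.
#' @param planted_motifs List of motif specs:
#'   \code{list(type = "ffl", signs = c(s_xy, s_yz, s_xz), gate = "AND"|"OR")}
#'   or \code{list(type = "fl", sign = +-1, length = k)}.
#' @param time_scale_distribution Weights over time scales 1..3.
#' @param seed Integer seed; the single source of randomness.
#' @return A \code{list} of class \code{lddr_genconfig}.
#' @export
generator_config <- function(n_components = 8L, max_level_fraction = 0.25,
                             n_terms = 12L, max_literals_per_term = 3L,
                             negation_probability = 0.3,
                             forbid_negative_cycles = FALSE,
                             forbid_positive_cycles = FALSE,
                             planted_motifs = list(),
                             time_scale_distribution = c(0.5, 0.35, 0.15),
                             seed = 1L) {
  stopifnot(max_level_fraction >= 0, max_level_fraction <= 1,
            negation_probability >= 0, negation_probability <= 1,
            length(time_scale_distribution) == 3L,
            all(time_scale_distribution >= 0))
  structure(list(n_components = as.integer(n_components),
                 max_level_fraction = max_level_fraction,
                 n_terms = as.integer(n_terms),
                 max_literals_per_term = as.integer(max_literals_per_term),
                 negation_probability = negation_probability,
                 forbid_negative_cycles = forbid_negative_cycles,
                 forbid_positive_cycles = forbid_positive_cycles,
                 planted_motifs = planted_motifs,
                 time_scale_distribution = time_scale_distribution,
                 seed = as.integer(seed)),
            class = "lddr_genconfig")
}

# components and terms realizing a planted motif on reserved node names
.plant_motif <- function(spec, idx, next_id) {
  if (spec$type == "ffl") {
    s <- spec$signs
    stopifnot(length(s) == 3L, all(s %in% c(-1L, 1L)))
    gate <- match.arg(spec$gate, c("AND", "OR"))
    nm <- sprintf("motif%d_%s", idx, c("x", "y", "z"))
    terms <- list(model_term(next_id, nm[2L],
                             literal(nm[1L], s[1L] < 0), 1L, 1L))
    if (gate == "AND") {
      terms[[2L]] <- model_term(next_id + 1L, nm[3L],
                                rbind(literal(nm[1L], s[3L] < 0),
                                      literal(nm[2L], s[2L] < 0)), 1L, 1L)
    } else {
      terms[[2L]] <- model_term(next_id + 1L, nm[3L],
                                literal(nm[1L], s[3L] < 0), 1L, 1L)
      terms[[3L]] <- model_term(next_id + 2L, nm[3L],
                                literal(nm[2L], s[2L] < 0), 1L, 1L)
    }
    list(nodes = nm, terms = terms,
         record = list(x = nm[1L], y = nm[2L], z = nm[3L],
                       s_xy = s[1L], s_yz = s[2L], s_xz = s[3L], gate = gate))
  } else if (spec$type == "fl") {
    k <- spec$length
    stopifnot(k >= 1L, spec$sign %in% c(-1L, 1L))
    nm <- sprintf("motif%d_c%d", idx, seq_len(k))
    terms <- lapply(seq_len(k), function(i) {
      src <- nm[if (i == 1L) k else i - 1L]
      # the single negated arc (if any) closes the cycle
      neg <- spec$sign < 0 && i == 1L
      model_term(next_id + i - 1L, nm[i], literal(src, neg), 1L, 1L)
    })
    list(nodes = nm, terms = terms,
         record = list(nodes = nm, sign = spec$sign))
  } else stop("unknown motif type: ", spec$type, call. = FALSE)
}

#' Generate a random multi-valued logical model
#'
#' Deterministic for a given config (same seed, same model). Planted motifs
#' occupy dedicated components that random wiring never touches, so a motif
#' census recovers each planted motif exactly once. Forbid flags are enforced
#' by rejection sampling (verified by cycle enumeration) with a bounded
#' number of attempts.
#'
#' @param config A [generator_config()].
#' @return A valid \code{lddr_model}. Attribute \code{planted} holds the
#'   planted motif records.
#' @export
random_model <- function(config) {
  stopifnot(inherits(config, "lddr_genconfig"))
  for (m in config$planted_motifs) {
    if (m$type == "fl" && m$sign < 0 && config$forbid_negative_cycles)
      stop("planted negative feedback loop contradicts forbid_negative_cycles",
           call. = FALSE)
    if (m$type == "fl" && m$sign > 0 && config$forbid_positive_cycles)
      stop("planted positive feedback loop contradicts forbid_positive_cycles",
           call. = FALSE)
  }
  withr::with_seed(config$seed, .random_model_impl(config))
}

.random_model_impl <- function(config, max_attempts = 25L) {
  planted <- lapply(seq_along(config$planted_motifs), function(i)
    .plant_motif(config$planted_motifs[[i]], i,
                 next_id = 1000L * i))
  motif_nodes <- unlist(lapply(planted, `[[`, "nodes"))
  motif_terms <- do.call(c, c(lapply(planted, `[[`, "terms"), list(list())))
  n_free <- config$n_components
  names_free <- sprintf("c%02d", seq_len(max(n_free, 0L)))
  all_names <- c(motif_nodes, names_free)

  n_tern <- round(config$max_level_fraction * n_free)
  tern <- if (n_tern > 0) sample(names_free, n_tern) else character()

  as_model <- function(terms) {
    comps <- do.call(rbind, lapply(all_names, function(nm)
      model_component(nm, if (nm %in% tern) 2L else 1L, 0L)))
    logical_model(comps, terms, outputs = character(), validate = FALSE)
  }
  violates <- function(terms) {
    if (!config$forbid_negative_cycles && !config$forbid_positive_cycles)
      return(FALSE)
    loops <- enumerate_feedback_loops(
      interaction_graph(as_model(terms)),
      max_length = length(all_names))
    signs <- vapply(loops, `[[`, integer(1), "sign")
    (config$forbid_negative_cycles && any(signs < 0)) ||
      (config$forbid_positive_cycles && any(signs > 0))
  }

  n_inputs <- max(1L, ceiling(n_free / 5L))
  inputs <- names_free[seq_len(min(n_inputs, n_free))]
  targets_pool <- setdiff(names_free, inputs)
  terms <- motif_terms
  next_id <- 1L
  gen_term <- function() {
    tgt <- sample(targets_pool, 1L)
    tgt_max <- if (tgt %in% tern) 2L else 1L
    nl <- sample(config$max_literals_per_term, 1L)
    srcs <- sample(names_free, min(nl, n_free))
    lits <- do.call(rbind, lapply(srcs, function(s0) {
      s_max <- if (s0 %in% tern) 2L else 1L
      literal(s0, stats::runif(1) < config$negation_probability,
              sample(s_max, 1L))
    }))
    model_term(next_id, tgt, lits,
               target_level = sample(tgt_max, 1L),
               time_scale = sample(3L, 1L,
                                   prob = config$time_scale_distribution))
  }
  # terms are drawn one by one; a term whose arcs would close a forbidden
  # cycle is redrawn a bounded number of times and then dropped
  for (k in seq_len(config$n_terms)) {
    if (!length(targets_pool)) break
    for (try in seq_len(max_attempts)) {
      tm <- gen_term()
      if (!violates(c(terms, list(tm)))) {
        terms[[length(terms) + 1L]] <- tm
        next_id <- next_id + 1L
        break
      }
    }
  }
  m <- as_model(terms)
  validate_model(m)
  attr(m, "planted") <- lapply(planted, `[[`, "record")
  m
}

#' Sample total states uniformly from a model's state space
#'
#' @param model A \code{lddr_model}.
#' @param n Number of states.
#' @param seed Integer seed.
#' @return List of named state vectors; same seed, same sample.
#' @export
state_sampler <- function(model, n, seed) {
  stopifnot(n >= 1L)
  comp <- model$components
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i)
      stats::setNames(vapply(comp$max_level, function(ml)
        sample(0:ml, 1L), integer(1)), comp$name))
  })
}
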