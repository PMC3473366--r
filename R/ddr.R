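# The DNA damage response models: the six-component core model with its five
# variants, the DDR priority scheme, scenario registry and comparison
# reports, and the full-model loader plus target/defect searches.

.CORE_ORDER <- c("DSBs_early", "DSBs_late", "RPA-ATR-ATRIP-P", "ATM-P",
                 "p53-P", "nuclear_p50-p65-P")

#' The six-component DDR core model
#'
#' The reduced DNA damage response network keeping only DSBs early, DSBs
#' late, RPA-ATR-ATRIP-P, ATM-P, p53-P and nuclear p50-p65-P. DSBs early is
#' the stimulus input; it activates ATM and, later, converts to resected late
#' breaks which assemble RPA-ATR-ATRIP; ATM and RPA-ATR-ATRIP each suffice to
#' activate p53; ATM activates nuclear NF-kB (p50-p65-P). The late negative
#' feedback layer — p53-driven Wip1/MDM2 dephosphorylating and degrading ATM
#' and p53, and NF-kB expressing its own inhibitor IkBa — survives reduction
#' as inhibiting self- and cross-arcs: p53 on ATM, p53 on itself, NF-kB on
#' itself. All negative feedback loops of the reduced graph contain p53 or
#' NF-kB; there is no positive loop.
#'
#' Variants interrupt the feedbacks: constitutive NF-kB or p53 clamp the
#' component at 1, deficiency clamps it at 0.
#'
#' @param variant One of \code{"wildtype"}, \code{"nfkb_constitutive"},
#'   \code{"p53_deficient"}, \code{"p53_deficient_nfkb_constitutive"},
#'   \code{"p53_constitutive"}, \code{"nfkb_deficient"}.
#' @return A \code{lddr_model} with components in the state-label digit
#'   order: DSBs early, DSBs late, RPA-ATR-ATRIP-P, ATM-P, p53-P, nuclear
#'   p50-p65-P.
#' @export
core_model <- function(variant = c("wildtype", "nfkb_constitutive",
                                   "p53_deficient",
                                   "p53_deficient_nfkb_constitutive",
                                   "p53_constitutive", "nfkb_deficient")) {
  variant <- match.arg(variant)
  comps <- do.call(rbind, lapply(.CORE_ORDER, function(nm)
    model_component(nm, 1L, 0L, annotation = "-P = phosphorylation")))
  terms <- list(
    model_term(1L, "DSBs_late", literal("DSBs_early"), 1L, time_scale = 2L),
    model_term(2L, "RPA-ATR-ATRIP-P", literal("DSBs_late"), 1L, 1L),
    model_term(3L, "ATM-P",
               rbind(literal("DSBs_early"), literal("p53-P", TRUE)), 1L, 1L),
    model_term(4L, "p53-P",
               rbind(literal("ATM-P"), literal("p53-P", TRUE)), 1L, 1L),
    model_term(5L, "p53-P",
               rbind(literal("RPA-ATR-ATRIP-P"), literal("p53-P", TRUE)),
               1L, 1L),
    model_term(6L, "nuclear_p50-p65-P",
               rbind(literal("ATM-P"), literal("nuclear_p50-p65-P", TRUE)),
               1L, 1L))
  m <- logical_model(comps, terms, outputs = character())
  clamps <- switch(variant,
    wildtype = NULL,
    nfkb_constitutive = c("nuclear_p50-p65-P" = 1L),
    p53_deficient = c("p53-P" = 0L),
    p53_deficient_nfkb_constitutive = c("p53-P" = 0L,
                                        "nuclear_p50-p65-P" = 1L),
    p53_constitutive = c("p53-P" = 1L),
    nfkb_deficient = c("nuclear_p50-p65-P" = 0L))
  if (!is.null(clamps)) m <- apply_clamps(m, clamps)
  m
}

#' The DDR priority scheme
#'
#' Rank 1: activations of RPA-ATR-ATRIP-P, ATM-P, p53-P and nuclear
#' p50-p65-P (the early signalling layer). Rank 2: activation of DSBs late by
#' DSBs early. Rank 3: the down-regulation of the rank-1 components
#' (initiation of feedback inhibition). Unlisted transitions get the lowest
#' rank.
#'
#' @return An \code{lddr_scheme}.
#' @export
ddr_priority_scheme <- function() {
  fast <- c("RPA-ATR-ATRIP-P", "ATM-P", "p53-P", "nuclear_p50-p65-P")
  priority_scheme(
    data.frame(component = fast, direction = "INCREASE",
               stringsAsFactors = FALSE),
    data.frame(component = "DSBs_late", direction = "INCREASE",
               stringsAsFactors = FALSE),
    data.frame(component = fast, direction = "DECREASE",
               stringsAsFactors = FALSE))
}

#' Damage-on initial state of the core model
#'
#' DSBs early present, everything else off — the state from which the
#' Figure-style state transition graphs are grown.
#'
#' @param model A core-model variant from [core_model()].
#' @return Named state vector.
#' @export
core_initial_state <- function(model = core_model()) {
  s <- stats::setNames(rep(0L, nrow(model$components)),
                       model$components$name)
  s[["DSBs_early"]] <- 1L
  # clamped components of a variant are inputs holding their clamp
  inp <- model$components$is_input
  s[model$components$name[inp]] <-
    pmax(s[model$components$name[inp]],
         model$components$default_level[inp])
  s[["DSBs_early"]] <- 1L
  s
}

#' Attractor analysis of a core-model variant
#'
#' Builds the prioritized state transition graph from the damage-on state
#' and classifies its attractors.
#'
#' @param variant Variant name (see [core_model()]).
#' @return List with the model, the STG and its attractors.
#' @export
core_attractors <- function(variant = "wildtype") {
  m <- core_model(variant)
  stg <- build_stg(m, core_initial_state(m), ddr_priority_scheme())
  list(model = m, stg = stg, attractors = find_attractors(stg))
}

#' Named scenario registry
#'
#' Scenarios of the published analyses: single-protein losses under a single
#' DNA-damage stimulus (validation tables; time scale 2), genetic disorders
#' with both stimuli (time scale 2, feedback investigations at 3), and the
#' carcinogenesis condition (both stimuli, no mutation). Component names
#' follow the full model's naming; the registry is declarative and is
#' resolved against a model only when a scenario is run.
#'
#' @return \code{data.frame} with columns name, mutation, mutation_level,
#'   stimuli, cutoff.
#' @export
scenario_registry <- function() {
  losses <- c("ATM-P", "ATR", "Chk1-P", "Chk2-P", "TAK1-P", "p53", "HIPK2")
  validation <- do.call(rbind, lapply(losses, function(p)
    data.frame(name = sprintf("%s_loss_%s", sub("-P$", "", p), c("ssb", "dsb")),
               mutation = p, mutation_level = 0L,
               stimuli = c("SSBs", "DSBs_early"), cutoff = 2L,
               stringsAsFactors = FALSE)))
  disorders <- data.frame(
    name = sprintf("disorder_%s", c("ATM", "Mre11", "Nbs1", "Rad50", "ATR")),
    mutation = c("ATM-P", "Mre11", "Nbs1", "Rad50", "ATR"),
    mutation_level = 0L, stimuli = "SSBs+DSBs_early", cutoff = 2L,
    stringsAsFactors = FALSE)
  carcino <- data.frame(name = "carcinogenesis", mutation = NA_character_,
                        mutation_level = NA_integer_,
                        stimuli = "SSBs+DSBs_early", cutoff = 2L,
                        stringsAsFactors = FALSE)
  rbind(validation, disorders, carcino)
}

#' Clamps of a registered scenario
#' @param model A \code{lddr_model} the scenario is run against.
#' @param name Scenario name from [scenario_registry()].
#' @return Named integer clamp vector (stimuli at 1, mutation at its level).
#' @export
scenario_clamps <- function(model, name) {
  reg <- scenario_registry()
  row <- reg[reg$name == name, , drop = FALSE]
  if (!nrow(row)) stop("unknown scenario: ", name, call. = FALSE)
  clamps <- integer()
  for (s in strsplit(row$stimuli, "+", fixed = TRUE)[[1L]])
    clamps[resolve_component(model, s)] <- 1L
  if (!is.na(row$mutation))
    clamps[resolve_component(model, row$mutation)] <- row$mutation_level
  clamps
}

#' Compare a scenario's steady state against a reference
#'
#' Runs [logical_steady_state()] for both clamp sets and reports per-component
#' level deltas plus per-output intact-pathway (active-term) counts, with the
#' verdict vocabulary of the validation tables: an output determined active
#' in the reference and forced to 0 in the scenario is \emph{blocked}; an
#' output still attainable whose intact-pathway count dropped is
#' \emph{diminished}.
#'
#' @param model A \code{lddr_model}.
#' @param clamps Scenario clamps (named integer vector).
#' @param reference_clamps Reference clamps (e.g. stimulus only).
#' @param cutoff Time-scale cutoff (default 2).
#' @param watch Components to report pathway counts for (default: the model's
#'   outputs).
#' @return List with \code{levels} (data.frame component, reference,
#'   scenario, delta) and \code{pathways} (data.frame component,
#'   reference_pathways, scenario_pathways, verdict).
#' @export
compare_scenarios <- function(model, clamps, reference_clamps, cutoff = 2L,
                              watch = NULL) {
  if (is.null(watch)) watch <- model$outputs
  ref <- logical_steady_state(model, reference_clamps, cutoff)
  scn <- logical_steady_state(model, clamps, cutoff)
  lv <- data.frame(component = model$components$name,
                   reference = as.integer(ref),
                   scenario = as.integer(scn),
                   stringsAsFactors = FALSE)
  lv$delta <- lv$scenario - lv$reference
  pw <- do.call(rbind, lapply(watch, function(w) {
    rp <- length(active_terms(model, ref, w, cutoff))
    sp <- length(active_terms(model, scn, w, cutoff))
    ref_on <- !is.na(ref[[w]]) && ref[[w]] >= 1L
    scn_off <- !is.na(scn[[w]]) && scn[[w]] == 0L
    verdict <- if (ref_on && scn_off) "blocked"
    else if (sp < rp) "diminished"
    else "unchanged"
    data.frame(component = w, reference_pathways = rp,
               scenario_pathways = sp, verdict = verdict,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pw))
    pw <- data.frame(component = character(), reference_pathways = integer(),
                     scenario_pathways = integer(), verdict = character(),
                     stringsAsFactors = FALSE)
  list(levels = lv, pathways = pw)
}

#' Load the transcribed full DDR model
#'
#' Reads a native-JSON transcription of the full model's logical functions
#' (the published supplementary table; not redistributable here) and
#' validates the documented structure: 96 components connected by 98
#' interactions, with exactly ATM-P, IKK_complex-P and IkBa ternary. A file
#' failing those checks is rejected.
#'
#' @param path Path to the transcription in the native JSON format.
#' @param strict Enforce the 96/98/ternary structure (default \code{TRUE};
#'   disable to load partial transcriptions for exploration).
#' @return A validated \code{lddr_model}.
#' @export
load_full_model <- function(path, strict = TRUE) {
  if (!file.exists(path))
    stop("full-model transcription not found at '", path, "'.\n",
         "Transcribe the published supplementary table of logical functions ",
         "into the native JSON format (see serialize_model()) and pass its ",
         "path.", call. = FALSE)
  m <- parse_model(path)
  if (strict) {
    errs <- character()
    if (nrow(m$components) != 96L)
      errs <- c(errs, sprintf("expected 96 components, found %d",
                              nrow(m$components)))
    if (length(m$terms) != 98L)
      errs <- c(errs, sprintf("expected 98 interactions, found %d",
                              length(m$terms)))
    tern <- sort(m$components$name[m$components$max_level == 2L])
    expected <- sort(c("ATM-P", "IKK_complex-P", "IκBα"))
    if (!identical(tern, expected))
      errs <- c(errs, sprintf("ternary components must be {%s}, found {%s}",
                              paste(expected, collapse = ", "),
                              paste(tern, collapse = ", ")))
    if (length(errs))
      stop("full-model validation failed:\n  - ",
           paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  m
}

#' Sensitization goal for a model
#'
#' Blocks cell cycle arrest and anti-apoptotic NF-kB while keeping the onset
#' of apoptosis switched on at the steady state.
#'
#' @param model A \code{lddr_model}.
#' @param arrest,nfkb,apoptosis Component names of the cell-cycle-arrest
#'   output, the anti-apoptotic NF-kB dimer, and the apoptosis-onset output.
#' @return An \code{lddr_goal}.
#' @export
sensitization_goal <- function(model, arrest = "CELL_CYCLE_ARREST",
                               nfkb = "nuclear_p50-p65-P",
                               apoptosis = "ONSET_OF_APOPTOSIS") {
  nms <- vapply(c(arrest, nfkb, apoptosis), function(n)
    resolve_component(model, n), character(1))
  goal_spec(require = stats::setNames(c(0L, 0L, 1L), nms))
}

#' Carcinogenesis (failure-mode) goal for a model
#'
#' Both phenotype outputs — onset of apoptosis and cell cycle arrest —
#' forced off, allowing damaged cells to proliferate.
#'
#' @inheritParams sensitization_goal
#' @return An \code{lddr_goal}.
#' @export
carcinogenesis_goal <- function(model, arrest = "CELL_CYCLE_ARREST",
                                apoptosis = "ONSET_OF_APOPTOSIS") {
  nms <- vapply(c(arrest, apoptosis), function(n)
    resolve_component(model, n), character(1))
  goal_spec(require = stats::setNames(c(0L, 0L), nms))
}

#' Sensitization-target search across the tumour-mutation scenarios
#'
#' For each mutated protein (p53, HIPK2, ATM, Chk2) and each stimulus (SSBs /
#' DSBs), enumerates minimal removal sets (cardinality <= 3, time scale 2)
#' fulfilling the sensitization goal, excluding the given components.
#'
#' @param model The full \code{lddr_model}.
#' @param excluded Components excluded from the candidate targets (curated
#'   exclusion list).
#' @param mutations Named integer vector list; defaults to the four published
#'   tumour mutations clamped at 0.
#' @param goal Optional goal override (default [sensitization_goal()]).
#' @param max_cardinality Maximum set size (default 3).
#' @return Named list (scenario -> list of minimal intervention sets).
#' @export
run_table3_search <- function(model, excluded = character(),
                              mutations = NULL, goal = NULL,
                              max_cardinality = 3L) {
  if (is.null(mutations))
    mutations <- list("p53" = c("p53" = 0L), "HIPK2" = c("HIPK2" = 0L),
                      "ATM" = c("ATM-P" = 0L), "Chk2" = c("Chk2-P" = 0L))
  if (is.null(goal)) goal <- sensitization_goal(model)
  stimuli <- c(ssb = "SSBs", dsb = "DSBs_early")
  out <- list()
  for (mn in names(mutations)) for (sn in names(stimuli)) {
    clamps <- mutations[[mn]]
    names(clamps) <- vapply(names(clamps), function(n)
      resolve_component(model, n), character(1))
    clamps[resolve_component(model, stimuli[[sn]])] <- 1L
    key <- sprintf("%s_%s", mn, sn)
    out[[key]] <- enumerate_mis(model, clamps, goal,
                                max_cardinality = max_cardinality,
                                excluded = c(excluded, names(clamps)),
                                cutoff = 2L)
  }
  out
}

#' Carcinogenic defect-combination search
#'
#' Under simultaneous SSBs and DSBs at time scale 2, enumerates minimal
#' combinations of constitutive activations and inactivations (cardinality
#' 1..3) that block both outputs.
#'
#' @param model The full \code{lddr_model}.
#' @param excluded Components excluded from the candidates.
#' @param goal Optional goal override (default [carcinogenesis_goal()]).
#' @param max_cardinality Maximum set size (default 3).
#' @return List of minimal defect combinations (named integer vectors).
#' @export
run_table5_search <- function(model, excluded = character(), goal = NULL,
                              max_cardinality = 3L) {
  if (is.null(goal)) goal <- carcinogenesis_goal(model)
  clamps <- stats::setNames(c(1L, 1L),
                            c(resolve_component(model, "SSBs"),
                              resolve_component(model, "DSBs_early")))
  cands <- intervention_candidates(model, "removal_activation",
                                   excluded = c(excluded, names(clamps)))
  # drop no-op clamps at the component's default level? No: a clamp freezes
  # the component, which is a defect even at the basal level for regulated
  # components; all attainable levels stay candidates.
  enumerate_mis(model, clamps, goal, max_cardinality = max_cardinality,
                candidates = cands, cutoff = 2L)
}
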