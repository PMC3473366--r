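test_that("the core model has the six published components in digit order", {
  m <- core_model()
  expect_identical(m$components$name,
                   c("DSBs_early", "DSBs_late", "RPA-ATR-ATRIP-P", "ATM-P",
                     "p53-P", "nuclear_p50-p65-P"))
  expect_true(m$components$is_input[m$components$name == "DSBs_early"])
  expect_true(all(m$components$max_level == 1L))
})

test_that("all core feedback loops are negative and functional", {
  m <- core_model()
  loops <- enumerate_feedback_loops(interaction_graph(m), 6L)
  expect_gt(length(loops), 0L)
  expect_true(all(vapply(loops, `[[`, integer(1), "sign") == -1L))
  expect_true(all(vapply(loops, function(l) is_functional(m, l),
                         logical(1))))
  # every loop contains p53 or NF-kB
  expect_true(all(vapply(loops, function(l)
    any(c("p53-P", "nuclear_p50-p65-P") %in% l$nodes), logical(1))))
})

test_that("core variants reproduce the published attractor kinds", {
  kinds <- list(wildtype = "COMPLEX_LOOP",
                nfkb_constitutive = c("SIMPLE_LOOP", "COMPLEX_LOOP"),
                p53_deficient = c("SIMPLE_LOOP", "COMPLEX_LOOP"),
                p53_deficient_nfkb_constitutive = "STEADY_STATE",
                p53_constitutive = "STEADY_STATE",
                nfkb_deficient = c("SIMPLE_LOOP", "COMPLEX_LOOP"))
  for (v in names(kinds)) {
    res <- core_attractors(v)
    expect_length(res$attractors, 1L)
    expect_true(res$attractors[[1L]]$kind %in% kinds[[v]],
                label = sprintf("%s kind", v))
  }
})

test_that("core fixed-point presence matches the attractor kinds", {
  # cyclic variants have no fixed point; steady-state variants exactly one
  damage <- c(DSBs_early = 1L)
  expect_length(steady_states_symbolic(core_model("wildtype"), damage), 0L)
  expect_length(steady_states_symbolic(core_model("p53_deficient"), damage),
                0L)
  expect_length(
    steady_states_symbolic(core_model("p53_deficient_nfkb_constitutive"),
                           damage), 1L)
  fps <- steady_states_symbolic(core_model("p53_constitutive"), damage)
  expect_length(fps, 1L)
  expect_identical(state_label(fps[[1L]]), "111010")
})

test_that("no core variant contains a functional positive feedback loop", {
  for (v in c("wildtype", "nfkb_constitutive", "p53_deficient",
              "p53_deficient_nfkb_constitutive", "p53_constitutive")) {
    m <- core_model(v)
    loops <- enumerate_feedback_loops(interaction_graph(m), 6L)
    pos <- Filter(function(l) l$sign == 1L, loops)
    expect_true(all(!vapply(pos, function(l) is_functional(m, l),
                            logical(1))) || length(pos) == 0L)
  }
})

test_that("the DDR priority scheme ranks activation before feedback decay", {
  sch <- ddr_priority_scheme()
  expect_length(sch$classes, 3L)
  expect_true(all(sch$classes[[1L]]$direction == "INCREASE"))
  expect_identical(sch$classes[[2L]]$component, "DSBs_late")
  expect_true(all(sch$classes[[3L]]$direction == "DECREASE"))
})

test_that("the scenario registry covers losses, disorders and carcinogenesis", {
  reg <- scenario_registry()
  expect_true(all(c("ATM_loss_dsb", "Chk1_loss_ssb", "disorder_Nbs1",
                    "carcinogenesis") %in% reg$name))
  expect_true(all(reg$cutoff == 2L))
  losses <- reg[grepl("_loss_", reg$name), ]
  expect_identical(nrow(losses), 14L)  # 7 proteins x 2 stimuli
})

test_that("scenario comparison maps deltas to blocked / diminished verdicts", {
  m <- two_pathway_model()
  ref <- c(S = 1L)
  # kinase loss: one of two pathways into OUT lost, output still on
  cmp <- compare_scenarios(m, c(S = 1L, K = 0L), ref)
  row <- cmp$pathways[cmp$pathways$component == "OUT", ]
  expect_identical(row$reference_pathways, 2L)
  expect_identical(row$scenario_pathways, 1L)
  expect_identical(row$verdict, "diminished")
  # upstream loss: output forced off
  cmp2 <- compare_scenarios(m, c(S = 1L, X = 0L, K = 0L), ref)
  expect_identical(cmp2$pathways$verdict[cmp2$pathways$component == "OUT"],
                   "blocked")
  expect_identical(cmp2$levels$delta[cmp2$levels$component == "OUT"], -1L)
})

test_that("equivalent subunit losses give identical reports", {
  # two subunits of one complex: either loss disables the complex the same way
  m <- logical_model(
    rbind(model_component("S"), model_component("Mre11"),
          model_component("Nbs1"), model_component("MRN"),
          model_component("OUT")),
    list(model_term(1L, "MRN", rbind(literal("S"), literal("Mre11"),
                                     literal("Nbs1")), 1L),
         model_term(2L, "OUT", literal("MRN"), 1L)),
    outputs = "OUT")
  # subunits are inputs (default 1 = present)
  m$components$default_level[m$components$name %in% c("Mre11", "Nbs1")] <- 1L
  ref <- c(S = 1L)
  c1 <- compare_scenarios(m, c(S = 1L, Mre11 = 0L), ref)
  c2 <- compare_scenarios(m, c(S = 1L, Nbs1 = 0L), ref)
  keep <- !(c1$levels$component %in% c("Mre11", "Nbs1"))
  expect_identical(c1$levels[keep, c("component", "scenario")],
                   c2$levels[keep, c("component", "scenario")])
  expect_identical(c1$pathways$verdict, c2$pathways$verdict)
})

test_that("the full-model loader enforces the documented structure", {
  expect_error(load_full_model(tempfile()), "transcription not found")
  # synthetic stand-in with the wrong shape is rejected with all failures
  tmp <- tempfile(fileext = ".json")
  write_model(chain_model(), tmp)
  err <- tryCatch(load_full_model(tmp), error = conditionMessage)
  expect_match(err, "96 components")
  expect_match(err, "98 interactions")
  expect_match(err, "ternary")
  # non-strict loading accepts partial transcriptions
  m <- load_full_model(tmp, strict = FALSE)
  expect_s3_class(m, "lddr_model")
})

test_that("table searches run end to end on a synthetic full-model stand-in", {
  # miniature stand-in with the full model's interface components
  m <- logical_model(
    rbind(model_component("SSBs"), model_component("DSBs_early"),
          model_component("p53"), model_component("HIPK2", 1L, 1L),
          model_component("ATM-P"), model_component("Chk2-P"),
          model_component("PP5"), model_component("casp"),
          model_component("CELL_CYCLE_ARREST"),
          model_component("nuclear_p50-p65-P"),
          model_component("ONSET_OF_APOPTOSIS")),
    list(model_term(1L, "ATM-P", rbind(literal("DSBs_early"),
                                       literal("PP5")), 1L),
         model_term(2L, "Chk2-P", literal("ATM-P"), 1L),
         model_term(3L, "CELL_CYCLE_ARREST", literal("Chk2-P"), 1L),
         model_term(4L, "CELL_CYCLE_ARREST", rbind(literal("p53"),
                                                   literal("SSBs")), 1L),
         model_term(5L, "nuclear_p50-p65-P", literal("ATM-P"), 1L),
         model_term(6L, "casp", literal("SSBs"), 1L),
         model_term(7L, "casp", literal("DSBs_early"), 1L),
         model_term(8L, "PP5", literal("DSBs_early"), 1L),
         model_term(9L, "ONSET_OF_APOPTOSIS", literal("casp"), 1L),
         model_term(10L, "p53", literal("HIPK2"), 1L)),
    outputs = c("CELL_CYCLE_ARREST", "ONSET_OF_APOPTOSIS"))
  t3 <- run_table3_search(m, mutations = list("p53" = c("p53" = 0L)))
  expect_named(t3, c("p53_ssb", "p53_dsb"))
  # DSB-only damage: blocking ATM-P shuts arrest and NF-kB, apoptosis stays
  expect_true("ATM-P" %in% format_mis(t3$p53_dsb))
  expect_true(all(vapply(t3$p53_dsb, function(iv)
    isTRUE(attr(iv, "minimal")), logical(1))))
  t5 <- run_table5_search(m, max_cardinality = 3L)
  expect_gt(length(t5), 0L)
  expect_true(all(lengths(t5) >= 1L))
})
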