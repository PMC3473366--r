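test_that("path signs compose through chains and branches", {
  g <- signed_graph(data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = c(1L, -1L),
    stringsAsFactors = FALSE))
  r <- signed_reachability(g)
  expect_false(r$positive["A", "C"])
  expect_true(r$negative["A", "C"])
  # two parallel routes of opposite sign
  g2 <- signed_graph(data.frame(
    source = c("A", "A", "C"), target = c("B", "C", "B"),
    sign = c(1L, -1L, 1L), stringsAsFactors = FALSE))
  r2 <- signed_reachability(g2)
  expect_true(r2$positive["A", "B"])
  expect_true(r2$negative["A", "B"])
})

test_that("parity reachability matches the walk-enumeration oracle", {
  for (seed in 1:30) {
    m <- random_small_model(seed, n = 8L, terms = 12L)
    g <- interaction_graph(m)
    expect_identical(signed_reachability(g), oracle_signed_reachability(g),
                     label = sprintf("seed %d", seed))
  }
})

test_that("dependency classes follow path signs and negative-cycle membership", {
  # acyclic chain: strong inhibitor
  g <- signed_graph(data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = c(1L, -1L),
    stringsAsFactors = FALSE))
  dm <- dependency_matrix(g)
  expect_identical(dm["A", "C"], "STRONG_INHIBITOR")
  expect_identical(dm["A", "B"], "STRONG_ACTIVATOR")
  expect_identical(dm["C", "A"], "NO_EFFECT")
  # negative self-loop on the intermediate makes the dependency weak
  g2 <- signed_graph(data.frame(
    source = c("A", "B", "B"), target = c("B", "C", "B"),
    sign = c(1L, 1L, -1L), stringsAsFactors = FALSE))
  dm2 <- dependency_matrix(g2)
  expect_identical(dm2["A", "C"], "WEAK_ACTIVATOR")
  expect_identical(dm2["B", "B"], "WEAK_INHIBITOR")
})

test_that("acyclic graphs contain no weak classes and classification is total", {
  for (seed in 1:15) {
    m <- random_small_model(seed, n = 7L, terms = 9L,
                            forbid_negative_cycles = TRUE,
                            forbid_positive_cycles = TRUE)
    dm <- dependency_matrix(interaction_graph(m))
    expect_false(any(grepl("WEAK", dm)))
    expect_true(all(dm %in% c("STRONG_ACTIVATOR", "WEAK_ACTIVATOR",
                              "STRONG_INHIBITOR", "WEAK_INHIBITOR",
                              "AMBIVALENT", "NO_EFFECT")))
  }
})

test_that("dependency classes match the exhaustive simple-path oracle", {
  for (seed in 1:20) {
    m <- random_small_model(seed, n = 6L, terms = 9L)
    g <- interaction_graph(m)
    expect_identical(unclass(dependency_matrix(g)),
                     oracle_dependency_matrix(g),
                     label = sprintf("seed %d", seed))
  }
})

test_that("classification is invariant under arc reordering", {
  m <- random_small_model(3L, n = 7L, terms = 11L)
  g <- interaction_graph(m)
  perm <- withr::with_seed(9L, sample(nrow(g)))
  g2 <- signed_graph(as.data.frame(g)[perm, , drop = FALSE],
                     nodes = graph_nodes(g))
  expect_identical(unclass(dependency_matrix(g)),
                   unclass(dependency_matrix(g2)))
})

test_that("feed-forward loops classify by coherence, type and gate", {
  # x -> y, y -| z, x -> z: incoherent (direct + vs indirect -)
  m <- logical_model(
    rbind(model_component("x"), model_component("y"), model_component("z")),
    list(model_term(1L, "y", literal("x"), 1L),
         model_term(2L, "z", literal("y", TRUE), 1L),
         model_term(3L, "z", literal("x"), 1L)))
  f <- enumerate_ffls(m)
  expect_identical(nrow(f), 1L)
  expect_identical(f$coherence, "INCOHERENT")
  expect_identical(f$type_index, 3L)  # (s_xy, s_yz) = (+, -)
  expect_identical(f$gate, "OR")      # x- and y-literals in distinct terms
  # AND gate: both literals in one term
  m2 <- logical_model(
    rbind(model_component("x"), model_component("y"), model_component("z")),
    list(model_term(1L, "y", literal("x"), 1L),
         model_term(2L, "z", rbind(literal("x"), literal("y")), 1L)))
  f2 <- enumerate_ffls(m2)
  expect_identical(f2$coherence, "COHERENT")
  expect_identical(f2$type_index, 1L)
  expect_identical(f2$gate, "AND")
})

test_that("OR-gated activation through a kinase relay is a coherent type-1 FFL", {
  # the p53 motif shape: ATM activates Chk2 and p53, Chk2 activates p53,
  # the two activators feeding p53 through distinct terms
  m <- logical_model(
    rbind(model_component("ATM-P"), model_component("Chk2-P"),
          model_component("p53-P")),
    list(model_term(25L, "Chk2-P", literal("ATM-P"), 1L),
         model_term(31L, "p53-P", literal("ATM-P"), 1L),
         model_term(32L, "p53-P", literal("Chk2-P"), 1L)))
  f <- enumerate_ffls(m)
  expect_identical(nrow(f), 1L)
  expect_identical(f$coherence, "COHERENT")
  expect_identical(f$type_index, 1L)
  expect_identical(f$gate, "OR")
})

test_that("planted FFLs are recovered exactly once with their classification", {
  cfg <- generator_config(
    n_components = 6L, n_terms = 8L, seed = 11L,
    planted_motifs = list(list(type = "ffl", signs = c(1L, -1L, -1L),
                               gate = "AND")))
  m <- random_model(cfg)
  f <- enumerate_ffls(m)
  hit <- f[f$x == "motif1_x" & f$y == "motif1_y" & f$z == "motif1_z", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$coherence, "COHERENT")  # (+)(-) = (-) = s_xz
  expect_identical(hit$type_index, 3L)
  expect_identical(hit$gate, "AND")
})

test_that("cycle enumeration equals exhaustive search on random graphs", {
  canon <- function(loops) {
    sort(vapply(loops, function(l)
      paste(c(l$nodes, l$sign), collapse = "|"), character(1)))
  }
  for (seed in 1:25) {
    m <- random_small_model(seed, n = 7L, terms = 11L)
    g <- interaction_graph(m)
    expect_identical(canon(enumerate_feedback_loops(g, 7L)),
                     canon(oracle_simple_cycles(g, 7L)),
                     label = sprintf("seed %d", seed))
  }
})

test_that("the NF-kB / inhibitor motif is one negative feedback loop", {
  # NF-kB drives the expression of its own inhibitor, which represses it
  m <- logical_model(
    rbind(model_component("p50-p65", 1L, 0L),
          model_component("IκBα", 1L, 0L)),
    list(model_term(1L, "IκBα", literal("p50-p65"), 1L),
         model_term(2L, "p50-p65", literal("IκBα", TRUE), 1L)))
  loops <- enumerate_feedback_loops(interaction_graph(m), 2L)
  expect_length(loops, 1L)
  expect_identical(loops[[1L]]$sign, -1L)
  expect_setequal(loops[[1L]]$nodes, c("p50-p65", "IκBα"))
  # positive 2-cycle for contrast
  loops2 <- enumerate_feedback_loops(interaction_graph(pos_two_cycle()), 2L)
  expect_identical(loops2[[1L]]$sign, 1L)
})

test_that("a loop with an AND co-factor is functional exactly when it is on", {
  # 2-cycle a <-> b where the arc a -> b requires co-factor c
  m <- logical_model(
    rbind(model_component("a"), model_component("b"), model_component("c")),
    list(model_term(1L, "b", rbind(literal("a"), literal("c")), 1L),
         model_term(2L, "a", literal("b", TRUE), 1L)))
  loop <- list(nodes = c("a", "b"), sign = -1L)
  ctx <- functionality_context(m, loop)
  expect_identical(nrow(ctx), 1L)
  expect_identical(ctx$c, 1L)
  expect_identical(ctx$.sign, -1L)
})

test_that("an arc shadowed by an always-on OR term kills functionality", {
  # b also has a constitutively satisfiable alternative via c; with c = 1 the
  # a -> b arc cannot change b's resolved level
  m <- logical_model(
    rbind(model_component("a"), model_component("b"), model_component("c")),
    list(model_term(1L, "b", literal("a"), 1L),
         model_term(2L, "b", literal("c"), 1L),
         model_term(3L, "a", literal("b", TRUE), 1L)))
  ctx <- functionality_context(m, list(nodes = c("a", "b")))
  expect_identical(nrow(ctx), 1L)
  expect_identical(ctx$c, 0L)  # functional only with the shadow off
})

test_that("functionality contexts agree with the state-space derivative oracle", {
  for (seed in 1:12) {
    m <- random_small_model(seed, n = 6L, terms = 9L)
    loops <- enumerate_feedback_loops(interaction_graph(m), 4L)
    loops <- unique(lapply(loops, `[[`, "nodes"))
    for (nodes in loops[seq_len(min(3L, length(loops)))]) {
      got <- functionality_context(m, list(nodes = nodes))
      want <- oracle_functional_contexts(m, list(nodes = nodes))
      ext <- attr(got, "externals")
      canon_got <- sort(vapply(seq_len(nrow(got)), function(r)
        paste(ext, unlist(got[r, ext]), collapse = ";"), character(1)))
      canon_want <- sort(vapply(want, function(K)
        paste(ext, K[ext], collapse = ";"), character(1)))
      expect_identical(canon_got, canon_want,
                       label = sprintf("seed %d loop %s", seed,
                                       paste(nodes, collapse = ",")))
    }
  }
})
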