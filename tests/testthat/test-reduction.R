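test_that("removing the middle of a kinase cascade links its ends directly", {
  m <- logical_model(
    rbind(model_component("MEK-P"), model_component("ERK-P"),
          model_component("p90-P")),
    list(model_term(1L, "ERK-P", literal("MEK-P"), 1L),
         model_term(2L, "p90-P", literal("ERK-P"), 1L)))
  r <- remove_component(m, "ERK-P")
  expect_setequal(r$components$name, c("MEK-P", "p90-P"))
  expect_length(r$terms, 1L)
  expect_identical(r$terms[[1L]]$target, "p90-P")
  expect_identical(r$terms[[1L]]$literals$component, "MEK-P")
  expect_false(r$terms[[1L]]$literals$negated)
})

test_that("autoregulated, input and output components are refused", {
  auto <- logical_model(
    rbind(model_component("A"), model_component("B")),
    list(model_term(1L, "B", rbind(literal("A"), literal("B", TRUE)), 1L)))
  expect_error(remove_component(auto, "B"), "autoregulated")
  expect_error(remove_component(auto, "A"), "input")
  m <- two_pathway_model()
  expect_error(remove_component(m, "OUT"), "output")
})

test_that("negated literals over the removed component invert its condition", {
  # X -| via NOT v where v = S: removing v must leave X = NOT S
  m <- logical_model(
    rbind(model_component("S"), model_component("v"), model_component("X")),
    list(model_term(1L, "v", literal("S"), 1L),
         model_term(2L, "X", literal("v", TRUE), 1L)))
  r <- remove_component(m, "v")
  for (s in 0:1) {
    st <- network_state(r, S = s)
    expect_identical(evaluate_target_level(r, "X", st), 1L - s)
  }
})

test_that("multi-valued thresholds expand correctly through removal", {
  # v ternary: level 1 from a, level 2 from a AND b; consumer fires on v >= 2
  m <- logical_model(
    rbind(model_component("a"), model_component("b"),
          model_component("v", 2L), model_component("X")),
    list(model_term(1L, "v", literal("a"), 1L),
         model_term(2L, "v", rbind(literal("a"), literal("b")), 2L),
         model_term(3L, "X", literal("v", FALSE, 2L), 1L)))
  r <- remove_component(m, "v")
  for (a in 0:1) for (b in 0:1) {
    st <- network_state(r, a = a, b = b)
    expect_identical(evaluate_target_level(r, "X", st),
                     as.integer(a == 1L && b == 1L),
                     label = sprintf("a=%d b=%d", a, b))
  }
})

test_that("removal preserves the truth table over kept components", {
  skipped <- 0L
  for (seed in 1:30) {
    m <- random_small_model(seed, n = 6L, terms = 9L)
    comp <- m$components
    removable <- comp$name[!comp$is_input]
    removable <- Filter(function(cn) !lddr:::.is_autoregulated(m, cn),
                        removable)
    if (!length(removable)) { skipped <- skipped + 1L; next }
    r <- remove_component(m, removable[[1L]])
    expect_true(oracle_truth_tables_agree(m, r),
                label = sprintf("seed %d, removed %s", seed, removable[[1L]]))
  }
  expect_lt(skipped, 15L)
})

test_that("reduce_to removes everything outside keep and projects fixed points", {
  # 4-node chain reduced to its endpoints
  m <- logical_model(
    rbind(model_component("A"), model_component("B"),
          model_component("C"), model_component("D")),
    list(model_term(1L, "B", literal("A"), 1L),
         model_term(2L, "C", literal("B"), 1L),
         model_term(3L, "D", literal("C"), 1L)))
  r <- reduce_to(m, c("A", "D"))
  expect_setequal(r$components$name, c("A", "D"))
  fp_full <- steady_states_symbolic(apply_clamps(m, c(A = 1L)))
  fp_red <- steady_states_symbolic(apply_clamps(r, c(A = 1L)))
  expect_length(fp_red, 1L)
  expect_identical(fp_red[[1L]][c("A", "D")], fp_full[[1L]][c("A", "D")])
})

test_that("a keep set stranding an autoregulated component is refused", {
  m <- logical_model(
    rbind(model_component("A"), model_component("B"), model_component("C")),
    list(model_term(1L, "B", rbind(literal("A"), literal("B", TRUE)), 1L),
         model_term(2L, "C", literal("B"), 1L)))
  expect_error(reduce_to(m, c("A", "C")), "autoregulated")
})

test_that("fixed points project exactly and their existence is preserved", {
  checked <- 0L
  for (seed in 1:40) {
    m <- random_small_model(seed, n = 7L, terms = 10L)
    comp <- m$components
    keep_req <- comp$name[comp$is_input |
                            vapply(comp$name, function(cn)
                              lddr:::.is_autoregulated(m, cn), logical(1))]
    drop_pool <- setdiff(comp$name, keep_req)
    if (length(drop_pool) < 2L) next
    keep <- setdiff(comp$name, drop_pool[seq_len(2L)])
    r <- tryCatch(reduce_to(m, keep), error = function(e) NULL)
    if (is.null(r)) next  # removal created a new autoregulation
    checked <- checked + 1L
    fp_full <- steady_states_symbolic(m)
    fp_red <- steady_states_symbolic(r)
    expect_identical(length(fp_full) == 0L, length(fp_red) == 0L,
                     label = sprintf("seed %d existence", seed))
    proj <- unique(lapply(fp_full, function(s) s[r$components$name]))
    canon <- function(l) sort(vapply(l, state_label, character(1)))
    expect_identical(canon(fp_red), canon(proj),
                     label = sprintf("seed %d projection", seed))
  }
  expect_gte(checked, 10L)
})

test_that("the removal order does not change the final truth tables", {
  for (seed in c(2L, 5L, 8L)) {
    m <- random_small_model(seed, n = 6L, terms = 9L)
    comp <- m$components
    pool <- setdiff(
      comp$name[!comp$is_input],
      Filter(function(cn) lddr:::.is_autoregulated(m, cn), comp$name))
    if (length(pool) < 2L) next
    two <- pool[seq_len(2L)]
    r12 <- tryCatch(remove_component(remove_component(m, two[1L]), two[2L]),
                    error = function(e) NULL)
    r21 <- tryCatch(remove_component(remove_component(m, two[2L]), two[1L]),
                    error = function(e) NULL)
    if (is.null(r12) || is.null(r21)) next
    for (s in enumerate_states(r12)) {
      for (cn in r12$components$name[!r12$components$is_input])
        expect_identical(evaluate_target_level(r12, cn, s),
                         evaluate_target_level(r21, cn, s[r21$components$name]),
                         label = sprintf("seed %d %s", seed, cn))
    }
  }
})
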