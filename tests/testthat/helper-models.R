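# Hand-built fixture models used across the suite.

# linear chain A -> B -> C (B's term at time scale 1, C's at `c_ts`)
chain_model <- function(c_ts = 1L) {
  logical_model(
    rbind(model_component("A"), model_component("B"), model_component("C")),
    list(model_term(1L, "B", literal("A"), 1L, 1L),
         model_term(2L, "C", literal("B"), 1L, c_ts)))
}

# negative 2-cycle: A -> B, B -| A
neg_two_cycle <- function() {
  logical_model(
    rbind(model_component("A"), model_component("B")),
    list(model_term(1L, "B", literal("A"), 1L, 1L),
         model_term(2L, "A", literal("B", TRUE), 1L, 1L)))
}

# positive 2-cycle: A -> B -> A
pos_two_cycle <- function() {
  logical_model(
    rbind(model_component("A"), model_component("B")),
    list(model_term(1L, "B", literal("A"), 1L, 1L),
         model_term(2L, "A", literal("B"), 1L, 1L)))
}

# ternary IkBa regulation: basal IKK partially degrades IkBa (2 -> 1),
# induced IKK degrades it fully (-> 0)
ikba_model <- function() {
  logical_model(
    rbind(model_component("IKK_complex-P", 2L, 1L),
          model_component("IκBα", 2L, 2L)),
    list(model_term(67L, "IκBα",
                    rbind(literal("IKK_complex-P", FALSE, 1L),
                          literal("IKK_complex-P", TRUE, 2L)), 1L, 1L),
         model_term(68L, "IκBα", literal("IKK_complex-P", FALSE, 2L),
                    0L, 1L)))
}

# stimulus -> two OR pathways into an output, one gated by a kinase
two_pathway_model <- function() {
  logical_model(
    rbind(model_component("S"), model_component("K", 1L, 1L),
          model_component("X"), model_component("OUT")),
    list(model_term(1L, "X", literal("S"), 1L, 1L),
         model_term(2L, "OUT", literal("X"), 1L, 1L),
         model_term(3L, "OUT", rbind(literal("S"), literal("K")), 1L, 1L)),
    outputs = "OUT")
}

random_small_model <- function(seed, n = 6L, terms = 9L, ...) {
  random_model(generator_config(n_components = n, n_terms = terms,
                                seed = seed, ...))
}
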