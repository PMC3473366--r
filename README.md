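# lddr — multi-valued logical modelling of DNA damage response signalling

`lddr` is an R engine for discrete logical models of signal transduction,
built around the DNA damage response (DDR): the network that decides, after
single- or double-strand DNA breaks, between cell cycle arrest, apoptosis,
and NF-κB-mediated survival. It is aimed at systems biologists who work with
curated logical models (the BoolNet / GINsim / CellNetAnalyzer tradition) and
want a scriptable, fully tested toolchain for:

- **multi-valued logical models** — components with activity levels 0/1/2,
  sum-of-products logical functions (hyperarcs of AND-connected literals,
  OR-connected alternatives), time-scale tags 1–3 on every interaction, and
  a native JSON interchange format with SIF/GraphML export;
- **logical steady states (LSS)** — the unique maximal set of activity
  levels forced by the functions under clamps (mutations, stimuli) and a
  time-scale cutoff, computed by three-valued propagation that is
  independent of update order; undetermined components are the signature of
  unresolved feedback;
- **structural analyses** — the dependency matrix classifying every ordered
  component pair as strong/weak activator or inhibitor, ambivalent, or no
  effect from path signs and negative-feedback-loop membership;
  feed-forward-loop censuses with Mangan–Alon type and AND/OR gate
  classification; feedback-loop enumeration with signs and GINsim-style
  functionality contexts;
- **asynchronous dynamics with priority classes** — state-transition graphs
  where transitions step one level toward each component's resolved target,
  ranked classes preempting slower events, with attractors detected as
  terminal strongly connected components and classified as steady state,
  simple loop, or complex loop;
- **attractor-preserving reduction** — removal of non-autoregulated
  components with exact rewriting of the consuming logical functions, so
  fixed points project exactly and fixed-point existence is preserved;
- **minimal intervention sets (MIS)** — subset-minimal combinations of
  clamps (knockouts, constitutive activations; cardinality ≤ 3) that achieve
  declarative goals, e.g. tumour sensitization (block cell cycle arrest and
  NF-κB, keep apoptosis onset intact) or carcinogenic failure modes (block
  both outputs);
- **a seeded synthetic-model generator** for property testing: controlled
  ternary fraction, density, signed-cycle content and planted motifs.

The package ships the six-component DDR core model (DSBs early, DSBs late,
RPA-ATR-ATRIP-P, ATM-P, p53-P, nuclear p50-p65-P) with its five variants and
the DDR priority scheme. The full 96-component model is defined by a
published supplementary table of logical functions that cannot be
redistributed here; `load_full_model()` validates a user-made transcription
(see `inst/extdata/README_transcription.md`) and the Table-style target and
defect searches run against it.

## Worked example

```r
library(lddr)

# the DDR core model and its damage-on dynamics
core <- core_model()
stg  <- build_stg(core, core_initial_state(core), ddr_priority_scheme())
att  <- find_attractors(stg)
length(att)          # 1
att[[1]]$kind        # "COMPLEX_LOOP"
length(att[[1]]$states)  # 8

# the complex cyclic attractor disappears when both feedback carriers are cut
both <- core_attractors("p53_deficient_nfkb_constitutive")
both$attractors[[1]]$kind    # "STEADY_STATE"
steady_states_symbolic(core_model("p53_constitutive"), c(DSBs_early = 1))
# [[1]] -> state 111010: damage processed, ATM and NF-kB off, p53 locked on

# every feedback loop of the core graph is negative and functional
loops <- enumerate_feedback_loops(interaction_graph(core))
vapply(loops, `[[`, integer(1), "sign")       # -1 -1 -1
vapply(loops, function(l) is_functional(core, l), logical(1))  # TRUE TRUE TRUE
```

The wildtype network under damage enters a single complex cyclic attractor
of 8 states — sustained, intertwined oscillation of ATM, p53 and NF-κB
driven by the three negative feedback loops. Interrupting p53 *and* fixing
NF-κB (or clamping p53 constitutively active) removes every functional
negative loop and the network settles into a single logical steady state
instead.

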