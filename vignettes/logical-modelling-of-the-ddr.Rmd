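---
title: "Multi-valued logical modelling of the DNA damage response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-valued logical modelling of the DNA damage response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lddr)
```

## The modelling formalism

`lddr` works with discrete logical models of signal transduction. Each
regulatory component (protein, modification state, damage species,
phenotype read-out) carries an activity level; most components are Boolean
(0 = inactive/absent, 1 = active/present), and components whose low and
high activities have different substrate spectra are ternary (0/1/2).
The canonical ternary cases in the DNA damage response (DDR) are
phosphorylated ATM, the phosphorylated IKK complex, and IκBα: basal IKK
activity (level 1) suffices for partial degradation of IκBα (2 → 1), while
damage-induced IKK activity (level 2) degrades IκBα fully (→ 0), releasing
the NF-κB dimers.

Regulation is written in sum-of-products form. A *term* (hyperarc) is an
AND-conjunction of literals — each literal tests one regulator against a
threshold, possibly negated — and states a sufficient condition for its
target to attain a given `target_level`. Terms sharing a target are
OR-connected alternatives. When several terms fire simultaneously, the
target resolves to the **maximum** fired `target_level`, and to its default
(basal) level when none fires. Inactivating interactions
(`target_level = 0`, e.g. degradation) are encoded so that they are the
only satisfiable term in their context; `find_term_conflicts()` flags
states where an inactivating and an activating term fire together, which a
curated model should never exhibit. A term with an empty literal list is
*constitutive* (always satisfied); the parser accepts this form because
model reduction can produce it when a removed component's level condition
is a tautology.

Every term carries a time-scale tag: 1 for the early signalling layer, 2
for interactions acting distinctly later (including those directly feeding
the phenotype outputs), 3 for the late feedback-initiating layer (e.g.
Wip1-mediated dephosphorylations). Time scales are cumulative: an analysis
at cutoff 2 uses all terms with tag ≤ 2, i.e. the network *before*
feedback inhibition comes into play. Most perturbation analyses in this
package default to cutoff 2 for that reason; cutoff 3 adds the feedback
layer.

The *signed interaction graph* is obtained by splitting each hyperarc into
one arc per literal, with arc sign = literal sign × term direction (the
direction is −1 for `target_level`-0 terms, which reproduces the T-arcs of
inhibiting interactions).

## Logical steady states

`logical_steady_state()` computes the values *forced* by the logical
functions under clamps (mutations at 0, constitutive activity at the
maximum level, stimuli at 1). The computation is three-valued: a
non-clamped component becomes determined exactly when every completion of
the current partial state yields the same resolved level. Because a
component's resolved level depends only on its own regulators, this is
decided exactly by enumerating completions of the undetermined regulators
(guarded at 65 536 completions per component — far above anything a curated
model's in-degree produces). The fixpoint is reached by iteration and is
independent of visitation order: determinations only accumulate, and a
value forced under fewer known regulators stays forced under more.

Components in unresolved feedback — e.g. a negative cycle without clamps —
remain undetermined rather than erroring: the *absence* of a total steady
state is exactly how cyclic attractors are inferred for models whose state
space is too large to explore dynamically. `active_terms()` reports which
terms of a component fire in a (partial) state, with undetermined literals
conservatively counted as not firing; the active-term count of an output is
the "number of intact pathways" idiom used in perturbation reports
(`compare_scenarios()` maps it to the *blocked* / *diminished* verdict
vocabulary: output forced to 0 → blocked; pathway count reduced while the
output stays attainable → diminished).

## Structural analyses

**Dependency matrix.** Every ordered pair (i, j) is classified from the
signs of the i → j paths and from negative-feedback-loop membership:
no path → no effect; both a positive and a negative path → ambivalent;
otherwise activator/inhibitor, *strong* if no species on any i → j path
(endpoints included) lies on a negative feedback loop, else *weak*. Path
signs deliberately use **simple paths** (`simple_path_signs()`), not walks:
under walk semantics a negative loop hanging off a pathway could always be
absorbed into a walk, every such dependency would collapse to ambivalent,
and the weak classes could never occur — contradicting their definition.
The walk-based parity closure is still exposed as `signed_reachability()`
(it answers "can influence at all, with which accumulated signs" and is
cheap), but classification and negative-cycle membership (a node on at
least one negative *simple* cycle) come from the simple-path census.
Simple-path enumeration is exponential in the worst case; curated
signalling networks are sparse enough that this is immaterial, and the test
suite pins the behaviour against an independent exhaustive oracle on random
graphs.

**Motifs.** `enumerate_ffls()` lists feed-forward loops x → y → z with
direct arc x → z, one record per sign combination where parallel arcs
exist. Coherence compares the direct sign with the product of the indirect
signs; the type index follows the Mangan–Alon convention on
(s\_xy, s\_yz): (+,+) → 1, (−,−) → 2, (+,−) → 3, (−,+) → 4. The gate of z
is AND when the x- and y-literals co-occur in one term, OR when they occur
only in distinct terms, MIXED otherwise. `enumerate_feedback_loops()`
returns all simple cycles up to a length bound (default 8 — reported
regulatory loops are short; raise it for exhaustive censuses of larger
graphs) with their signs, self-loops included.

**Functionality contexts.** A feedback loop can only drive oscillations
(negative sign) or multistability (positive sign) if it is *functional*:
some assignment of its external regulators lets every loop arc actually
change its target. `functionality_context()` enumerates those assignments;
an arc u → v counts as functional in a context when stepping u across some
threshold changes v's resolved level for some assignment of v's remaining
loop-internal regulators. The context-dependent loop sign is the product of
the arc derivative signs (NA when an arc's derivative sign is mixed within
the context). The definition is pinned against a whole-state-space
discrete-derivative oracle in the tests.

## Asynchronous dynamics with priority classes

State transitions move one component one level toward its resolved target
(±1 — the standard multi-valued asynchronous convention, needed so a
ternary component passes through its intermediate level). Transitions are
grouped into ranked priority classes keyed by (component, direction);
at each state only the candidates of the highest-ranked class fire,
asynchronously within the class — all successors are kept, no random
scheduling. Unlisted pairs fall into the lowest rank. The DDR preset
(`ddr_priority_scheme()`) has rank 1 = activation of RPA-ATR-ATRIP, ATM,
p53 and nuclear NF-κB; rank 2 = conversion of early to late DSBs; rank 3 =
the down-regulation of the rank-1 components, i.e. the feedback layer.

`build_stg()` grows the reachable state-transition graph (with a
configurable guard, default 10^6 states, raising an explicit overflow
error); `find_attractors()` extracts terminal strongly connected components
and classifies them: steady state (singleton, no exit), simple loop (every
member exactly one successor), complex loop (branching). State labels are
digit strings in declared component order, so the core model's states read
as the six-digit vectors of the published figures.

`steady_states_symbolic()` finds all total fixed points without building
the graph, by backtracking over component levels with constraint
propagation (components ordered by distance from the inputs so conflicts
surface early). Fixed points are updating-scheme independent, which is what
licenses the inference "no fixed point ⇒ cyclic attractor" for large
models.

## Attractor-preserving reduction

`remove_component()` eliminates a component by substituting its
target-level function into every consuming literal: the condition
"level(v) ≥ t" expands to *some term with target ≥ t fires, or no term
fires and the default is ≥ t*, expressed in disjunctive normal form and
distributed back into the consuming terms (simplification is absorption
plus duplicate and contradiction removal only — no full minimisation, so
the rewriting stays auditable). Autoregulated components are refused: a
feedback loop reduces at most to an autoregulation, and removing it would
lose loops and attractors. Inputs and outputs are likewise kept. The
time-scale tag of a merged term is the maximum of the merged tags — a path
is as late as its latest step; this is a conservative repo convention, as
the source formalism leaves merged tags unspecified.

`reduce_to()` iterates removals outside a keep-set in a deterministic order
(fewest regulators first, ties alphabetical — the removal order is not
specified by the formalism either, and an order-permutation property test
confirms the final truth tables do not depend on it). What reduction
guarantees — and what the tests assert — is: identical truth tables of kept
components with the removed variables resolved, exact projection of fixed
points, and preservation of fixed-point existence. Trajectories of the full
state-transition graph may be lost, so no STG isomorphism is claimed.

## Minimal intervention sets

`enumerate_mis()` searches all clamp sets up to a cardinality bound
(default 3) over a candidate pool — removals (clamp 0) of non-input,
non-output components for sensitization searches; removals *and*
constitutive activations at every attainable level for failure-mode
searches — and reports the subset-minimal ones, pruning supersets as it
goes. The empty set participates in the subset order: when the scenario
alone already satisfies the goal (an ATM-deficient background under
double-strand breaks meets the sensitization goal by itself), no nonempty
set is minimal and the result is empty — "no targets". Goals are
declarative (`goal_spec()`): required determined levels, plus optional
any-of alternatives; an undetermined level never satisfies a requirement.
The sensitization preset requires the cell-cycle-arrest output and
anti-apoptotic NF-κB at 0 with the onset-of-apoptosis output determined at
1; the carcinogenesis preset forces both outputs to 0. Both headline
searches run at time-scale cutoff 2.

## The DDR core model

The six-component core network (DSBs early → DSBs late → RPA-ATR-ATRIP;
DSBs early → ATM; ATM and RPA-ATR-ATRIP each activating p53; ATM activating
nuclear NF-κB) descends from reducing the full curated DDR model. The full
model's functions live in a supplementary table that cannot be shipped
here, and the reduced model's functions are not printed either, so
`core_model()` reconstructs them from the published core topology and the
described feedback structure: the p53–Wip1/MDM2 feedbacks survive reduction
as an inhibiting p53 self-arc and a p53 ⊣ ATM arc, and the NF-κB–IκBα loop
as an inhibiting NF-κB self-arc. Written as functions (E = DSBs early,
L = late, R = RPA-ATR-ATRIP, A = ATM, P = p53, N = nuclear NF-κB):

    L = E          R = L          A = E AND NOT P
    P = (A OR R) AND NOT P        N = A AND NOT N

This is the simplest sum-of-products realisation of that topology, and it
reproduces the published dynamics exactly: under the DDR priority scheme
from the damage-on state, the wildtype enters a single 8-state complex
cyclic attractor; constitutive NF-κB, p53 deficiency, or NF-κB deficiency
still yield a single cyclic attractor; p53 deficiency *plus* constitutive
NF-κB, or constitutive p53 alone, yield a single logical steady state. All
three feedback loops of the core graph are negative and functional, every
loop contains p53 or NF-κB, and no variant has a functional positive loop —
hence the single attractor per variant. Where a transcription of the full
model is available, `reduce_to()` on it can be compared against this
reconstruction; discrepancies are reported by the equivalence test rather
than silently resolved.

Variants encode mutations by clamping: "deficient" = 0, "constitutively
active" = the maximum level; clamped components become held inputs.

## The synthetic model suite

`random_model()` generates models of the same structural class as the
curated DDR network: a minority of ternary components (default fraction
0.25), sparse sum-of-products terms of 1–3 literals, negation probability
0.3, time-scale weights (0.5, 0.35, 0.15) mirroring a thick early layer and
a thin late feedback layer, and roughly one input per five components.
Cycle-content flags are enforced by redrawing terms whose arcs would close
a forbidden cycle (verified post hoc by cycle enumeration), and planted
motifs occupy dedicated components that random wiring never touches, so a
census recovers each planted motif exactly once. A single integer seed
controls all randomness through a scoped RNG, leaving the session's RNG
state untouched.

The generator emulates *structure*, not biology: it does not produce
curated conflict-free inactivation contexts, realistic in/out-degree
correlations, or meaningful defaults. Property tests on it therefore
establish the correctness of the algorithms (order independence,
brute-force agreement, motif census completeness, reduction invariants,
the negative-cycle/oscillation and positive-cycle/multistability
necessities), not the biological fidelity of any particular model.

## Problem sizes and numerical choices

The property suite runs models of 5–8 components against exhaustive
oracles — enumeration over completions for steady states, all simple paths
and cycles for the structural layer, full subset search for intervention
sets, whole truth tables for reduction — with 10–200 seeds per property;
these sizes keep exhaustive oracles exact while exercising every code
path, and the whole suite completes in well under a minute. Guards are
explicit everywhere growth is exponential: completions per component
(65 536), STG states (10^6), functionality-context assignments (3^10),
cycle length (8). Ties are broken deterministically throughout (term ids,
lexicographic orders), so every analysis is reproducible run to run.

## Limitations

- The full 96-component model requires a user-supplied transcription of
  its published supplementary function table; without it the full-model
  searches and their published counts (85 sensitization sets, 117 defect
  combinations) cannot be recomputed, and the corresponding checks report
  that absence rather than skipping silently.
- Dependency classification and cycle enumeration are exponential-worst-case
  by design (simple-path semantics); they target curated, sparse networks.
- Reduction preserves attractor *existence* classes via fixed points, not
  trajectories; transient behaviour of a reduced model is not evidence
  about the full model.
- Quantitative kinetics, stochastic scheduling and model-checking queries
  are out of scope.
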