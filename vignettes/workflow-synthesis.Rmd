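---
title: "Methods: type-driven synthesis and verification of service workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: type-driven synthesis and verification of service workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowsynth)
```

This vignette is the package's own account of its method: the model and
its assumptions, the semantic choices that were genuinely open and how
they were resolved, what the bundled fixtures and the random-domain
generator do and do not exercise, and the known limitations.

## Domain models and subsumption

Everything in `flowsynth` is symbolic. A service is a pair of type-name
sets — inputs and outputs — and carries no executable payload; types are
opaque tokens. The semantic glue is a pair of taxonomies: acyclic `is-a`
hierarchies of abstract classes rooted at a most-general class (`Thing`),
with concrete names attached by `instance-of` links (possibly to several
classes at once, e.g. a multiple nucleotide sequence is both a
`MultipleSequence` and a `NucleotideSequence`). Subsumption is the
reflexive–transitive closure of `instance-of` followed by `is-a`.

Two matching conventions deserve justification, because both directions
are a priori conceivable:

* **A state member satisfies a requirement when the requirement subsumes
  the member** (specific satisfies general). This is the only direction
  under which a concrete `MultipleNucleotideSequence` satisfies an
  aligner's abstract `MultipleSequence` input, which the curated example
  domain depends on.
* **Requirements may themselves be abstract class names.** The curated
  domain uses class-valued inputs (`Sequence`, `ProteinSequence`), and
  the automatically derived domain types inputs by ontology term names,
  which are classes of the derived taxonomy. Concrete-valued requirements
  degenerate gracefully: a concrete name subsumes only itself.

All declared inputs are mandatory. ACD descriptors do distinguish
mandatory from optional parameters, but the input/output tables the
package reproduces are flat sets; optional-parameter semantics is simply
not represented in the model.

`validate_domain()` reports diagnostics rather than raising errors, so a
broken domain can be inspected as a whole. The never-applicable-service
check runs only against explicitly supplied start states: a domain
declares no starts of its own, and a service that is unreachable from an
*empty* state (e.g. a database searcher whose database type no service
produces) is still perfectly usable in workflows whose upstream provides
that type. With no starts given, the check is skipped.

## Execution semantics and the configuration universe

A state is the set of currently available types; executing an applicable
service unions in its outputs. States therefore grow monotonically along
any execution — the package's property tests assert this on every
returned solution — and applicability is monotone in the state. The
implicit transition system over all type subsets (the configuration
universe) is never materialized; the search expands it on the fly and
interns states by content.

## Temporal logic over finite traces

Constraints are evaluated on finite traces `s0, a1, s1, ..., an, sn`
with positions `0..n`:

* `f_exec(C)` holds at position `i < n` iff the service executed next is
  subsumed by `C` in the *service* taxonomy; it is false at position `n`.
  An abstract class atom is thus exactly equivalent to the disjunction of
  its instances (a tested invariant).
* `f_avail(T)` holds at `i` iff state `s_i` satisfies requirement `T`.
* `end` holds exactly at position `n`; `X` is the strong next (false at
  `n`); `WU` is weak until, `G(p) | (p U q)` (tested exhaustively against
  that expansion on all traces of a small domain to depth 4).

Finite-trace semantics with an explicit `end` atom was chosen because
solutions *are* finite sequences; weak next is expressible as
`!X true | X p`. One consequence is deliberate: "Use X as last service in
solution" translates to `F (X_svc & X end)`, which is **false on the
empty sequence** — there is no last service — so such a constraint forces
at least one step even when the goal is already satisfied.

Templates are intentionally a tiny fixed set (enforce-use, use-as-last,
do-not-use, use-before). The first two are the load-bearing ones; the
other two are declared conveniences. Unknown names in a template produce
an error listing the nearest known names by edit distance, since typos in
service names are the dominant failure mode.

## The synthesis search

`synthesize()` runs breadth-first over pairs *(state, residual formula)*.
The residue is computed by formula progression: consuming one position
decides the atoms against the current state and action and unfolds the
modalities one step (`F p` into `p' | F p`, and so on), followed by
constant folding. A sequence is emitted when the goal types are satisfied
in its final state *and* the residue is accepted at the trace end
(`end` true, `exec` atoms false, strong next false). Progression-based
acceptance is itself property-tested against direct trace evaluation on
random formulas and traces.

Three design points matter for fidelity and reproducibility:

* **Front entries with equal (state, residue) pairs are merged, never
  pruned.** Their continuations are identical, so merging is lossless;
  pruning revisited pairs would lose alternative prefixes and break the
  package's central correctness claim, `synthesize()` ≡
  `brute_force_oracle()` (set-and-order equality per length, checked on
  the fixture problems and 200 seeded random domains). Degenerate
  repetitions such as applying the same sink twice are *valid* solutions
  of the bounded enumeration and are kept.
* **Deterministic ordering**: solutions are ordered by length, ties
  broken lexicographically by service-name sequence. An interactive
  front end would let the user pick; a library and CLI need a stable
  order.
* **Bounds**: `depth_bound` defaults to 6 and `solution_cap` to 1000.
  In realistic domains many tools consume and produce near-identical
  types, so the solution set explodes combinatorially with the bound; the
  cap is not an optimization but a necessity. Per-front prefix lists are
  truncated at the cap, so at most `solution_cap` solutions are ever
  reported and memory stays bounded.

The brute-force oracle is kept deliberately naive — enumerate every
applicable sequence, replay it, evaluate the conjoined constraints by the
direct semantics — so that it shares no code path with the search it
checks.

Start types for a loose branch are inferred by data-flow analysis: the
intersection, over all simple control-flow paths from the workflow's
initial node to the branch's source node (inclusive), of the accumulated
output types along each path. Intersection is the only sound choice under
branching (a type produced on just one incoming branch is not
guaranteed); simple paths suffice because revisiting a node cannot remove
types.

## Verification semantics

`check_process()` labels every node of a loose-free process graph with a
verdict: the formula must hold on *every* maximal control-flow path
starting at that node. This per-node universal reading is what makes a
single offending node stand out (the build step of an uncalibrated HMM
chain) while its neighbours stay green. Atoms are node-labelled — the
position's atom is the node's own service, so the initial position sees
the starting node itself — and a finite maximal path `n1..nk` is
evaluated as the action trace `a1..ak` with `end` holding after the sink,
which makes chain verdicts at the initial node coincide exactly with
trace evaluation (a tested invariant).

Loops are handled by lasso enumeration: depth-first exploration in which
a node may occur at most twice on the current path; revisiting a node
closes a lasso there, and continuing one level deeper also covers loops
that combine two simple cycles. Lasso traces are evaluated with standard
infinite-trace fixpoint semantics (`U`/`F` as least, `WU`/`G` as greatest
fixpoints of their one-step unfoldings over the lasso). This is complete
for the workflow-sized graphs and guarded properties the package targets;
a pathological combination of formula and graph whose only counterexample
needs a loop visiting some node three or more times before repeating
would be missed. Type-availability atoms are rejected in process
checking: a process graph carries control flow, not data states.

## The derived domain: reconstruction decisions

`build_auto_domain()` mirrors a three-step pipeline: grow taxonomy
skeletons from an ontology's data and operation branches, extract
input/output behavior from ACD files, and link both to the annotated
ontology terms. The bundled ACD and OBO files are *synthetic
reconstructions* written for this package (real ACD syntax, miniature
EDAM-style term set); they are fixtures, not copies of upstream data.

Input parameters are typed by their annotation's term name — a class of
the derived type taxonomy — and an annotation naming a term outside the
ontology (e.g. `sequence_alignment_data`, which the miniature ontology
deliberately lacks, mirroring gaps in real annotation sets) contributes a
class directly under the root. Output parameters are named by the first
applicable rule:

1. a sanitized `knowntype` attribute (`"hmmcalibrate output"` →
   `hmmcalibrate_output`, `"hmm"` → `hmm`) — ACD files name output types
   after the original program names, which is why an application called
   `ehmmcalibrate` yields an output type called `hmmcalibrate_output`;
2. an annotation resolving to a *leaf* data class, used directly as the
   type;
3. the fallback pattern `<application>_<parameter>_output`.

Knowntype- and pattern-named outputs become instances of their
annotation's class when one resolves, else direct instances of the root —
in the bundled set the majority of derived entities indeed sit directly
under the root, which is precisely why the derived domain finds no
solution for branches the curated domain closes easily: the aligners'
outputs are annotated only as `sequence_record`, never as the
`sequence_alignment_data` the alignment viewer requires. That asymmetry
is the package's central illustration that automatic domain construction
is only as good as the annotations it consumes.

Several annotations carry only a term label and no identifier, and one
tool is modelled with no output section at all; the importer accepts
both, because real annotation sets contain exactly these irregularities.
Multiple application-level annotations use the first for service
placement.

## The random-domain generator

`generate_random_domain()` emulates the *shape* of curated domains:
a shallow random class hierarchy (depth ≤ 2 by default), 6 concrete
types, 8 services with up to 2 inputs and outputs each, class-valued
requirements and abstract service groups appearing with probability 0.5,
and always at least one no-input source so non-trivial problems exist.
Generation is a pure function of the spec (RNG state is saved and
restored), so every test failure is reproducible from its seed.

What it does **not** emulate: real domains have long type tails, near-
duplicate tools, and annotation noise; the generator's universes are
small enough that the brute-force oracle stays exact. Passing the
property sweep therefore demonstrates algorithmic correctness
(completeness to the bound, ordering, soundness, optimality), not
performance or modelling adequacy on full-scale suites.

Problem sizes used by the shipped tests: the oracle sweep runs 200
domains (≤ 8 services, ≤ 6 types) at depth bounds 2–4 with a 500-solution
cap; exhaustive trace enumerations for the semantics invariants go to
depth 4 on a 4-service domain. These sizes keep the oracle exact while
exercising every code path; the synthesis search itself handles the
17-service fixtures at bound 6 in well under a second.

## Known limitations

* No optional inputs, no costs: solution ranking is length-then-name;
  a cost-based "cheapest solution" hook would slot into the emission
  ordering but is not implemented.
* OWL-style reasoning is out of scope — taxonomies are `is-a` /
  `instance-of` closures only, and ontology import reads OBO, not OWL.
* Verification is LTL-only (no branching-time logic), per-node, with the
  lasso-enumeration caveat above; counterexamples are reported but not
  minimized.
* The synthesis enumerates concrete sequences; solutions differing only
  in which instance of an abstract group they use are distinct solutions.
* Services are opaque: nothing is executed, and real data-format
  compatibility is assumed to be handled by the tool layer underneath.
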