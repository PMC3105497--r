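# flowsynth

Semantics-based composition and verification of bioinformatics service
workflows.

Suites like EMBOSS bundle hundreds of command-line tools whose inputs and
outputs are mutually compatible, but finding the right chain of tools for a
given analysis is hard to do by hand. `flowsynth` implements a
workflow-composition methodology for such collections: services are
described purely *symbolically* by sets of input and output type names,
types and services are classified in small ontologies (taxonomies of
`is-a` classes with `instance-of` members), and underspecified ("loose")
branches of a workflow are completed automatically by a temporal-logic
constrained search. Fully concretized workflows can then be model-checked
against linear-time properties, node by node.

The package is aimed at people building or studying semantic service
registries and workflow managers: it lets you author a domain model by
hand, derive one automatically from EMBOSS ACD tool descriptors linked to
an OBO ontology such as EDAM, and compare what each setup can and cannot
infer.

## The model

A **domain** is a set of services *s*, each with input types
*in(s) ⊆ T* and output types *out(s) ⊆ T*, plus a type taxonomy and a
service taxonomy. A **state** is a set of available types; service *s* is
applicable in state *S* when every *t ∈ in(s)* is satisfied by some
member of *S* under taxonomy subsumption (a concrete type satisfies an
abstract requirement when the requirement subsumes it), and executing *s*
moves the system to *S ∪ out(s)*. This implicit transition system — the
**configuration universe** — is searched breadth-first, in parallel with a
specification formula in linear temporal logic over finite traces
(`F G X U WU`, plus taxonomy-aware atoms for "service of class *C* is
executed here" and "a type satisfying *T* is available"). The formula is
evaluated by *progression*: each expansion step rewrites the constraint
into the residue the remaining suffix must satisfy, so search states are
(type-set, residue) pairs. A service sequence is a **solution** of a loose
branch when it is type-consistent, reaches the downstream service's input
types, and its full trace satisfies the conjoined constraints. Constraints
are written as natural-language templates ("Enforce the use of module X",
"Use X as last service in solution", ...) or as raw formulas.

Verification answers a different question: given a concrete process graph
and a PLTL formula such as

```
ehmmbuild => (!ehmmemit WU ehmmcalibrate)
```

("a built HMM must be calibrated before sequences are emitted"), every
node is labelled `holds`/`violated` according to whether the formula holds
on *all* maximal control-flow paths from that node — finite paths with
finite-trace semantics, loops with lasso (infinite-trace) semantics.

## Worked example

The bundled example domain is the HMMER subset of EMBOSS: 17 services
(9 HMMER profile-HMM tools, the aligners `emma` and `edialign`, sequence
generators, and display tools) in two setups — one curated by hand, one
derived from the ACD/ontology fixtures shipped under `inst/extdata/`.

```r
library(flowsynth)

domain  <- load_fixture("manual_hmmer")
process <- load_fixture("align_view_process")   # makenucseq -(loose)-> showalign

problem <- problem_from_loose_edge(process, 1, domain, depth_bound = 4)
problem
#> <synthesis problem> start {MultipleNucleotideSequence} -> goal {Alignment}; 0 constraint(s); bound 4

synthesize(problem, shortest_only = TRUE)
#> [[1]]  <solution> [edialign]
#> [[2]]  <solution> [emma]
```

The loose branch from a random-nucleotide generator to an alignment
viewer is closed by a single multiple-alignment service: the start types
are inferred by data-flow analysis (`MultipleNucleotideSequence`, the
generator's output), the goal is the viewer's input (`Alignment`), and
`MultipleNucleotideSequence` satisfies the aligners' abstract
`MultipleSequence` requirement through the type taxonomy. Splicing a
solution back yields the concrete three-node workflow
(`makenucseq -> emma -> showalign`). Running the same branch against the
automatically derived domain (`load_fixture("auto_hmmer")`) returns *no*
solution at any bound: in that setup the aligners' outputs are annotated
only as `sequence_record`, never as the `sequence_alignment_data` the
viewer demands — the disconnect is in the metadata, not in the method.

Model checking the calibration policy on the chain
`emma -> ehmmbuild -> ehmmemit -> showseq`:

```r
check_process(load_fixture("hmm_emit_chain"),
              "ehmmbuild => (!ehmmemit WU ehmmcalibrate)", domain)
#> <verdict> (ehmmbuild => (! ehmmemit WU ehmmcalibrate))
#>   [ok] emma
#>   [X ] ehmmbuild
#>        witness: ehmmbuild -> ehmmemit -> showseq
#>   [ok] ehmmemit
#>   [ok] showseq
```

Only the build step violates the policy; inserting `ehmmcalibrate`
(`load_fixture("hmm_emit_chain_calibrated")`) makes it hold at every node, and a
variant that fetches the HMM from a database instead of building it holds
vacuously.

## Package layout

| Area | Files |
| --- | --- |
| Domain model, taxonomies, states | `R/taxonomy.R`, `R/domain.R`, `R/domain_io.R` |
| ACD / OBO importers, derived domains | `R/acd.R`, `R/obo.R`, `R/auto_domain.R` |
| Temporal logic: AST, parser, semantics | `R/formula.R`, `R/templates.R`, `R/evaluate.R` |
| Synthesis search + oracle | `R/synthesis.R` |
| Process graphs and model checking | `R/process.R`, `R/verification.R` |
| Fixtures, random domains, CLI | `R/fixtures.R`, `R/random_domain.R`, `R/cli.R` |

The methods vignette (`vignettes/workflow-synthesis.Rmd`) documents the
semantics, the reconstruction decisions behind the derived domain, and
the package's limitations.
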