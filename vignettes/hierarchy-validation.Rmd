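---
title: "Validating expert term hierarchies and building simplified ontology views"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating expert term hierarchies and building simplified ontology views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoview)
library(dplyr)
```

## The problem

Atlas projects routinely collect expert knowledge about anatomy and cell
types in spreadsheets: each row of an ASCT+B-style table nests anatomical
structures (AS) left to right from organ to substructure, attaches cell
types (CT) to the most specific structure, and attaches biomarkers (B) to
cell types. Adjacency encodes a hierarchical relationship, but not *which*
relationship — and only a subset of relationship types (subsumption,
parthood and its subproperties) is safe for grouping annotations by
location. A cell type recorded under the generic term "endothelium", for
instance, silently claims that *all* endothelium is part of that structure,
which is false and corrupts location queries.

Reference ontologies such as Uberon and the Cell Ontology carry the missing
logic: formally defined relations (`part_of` BFO:0000050, `overlaps`
RO:0002131, `connected_to` RO:0002170, `develops_from` RO:0002202, ...),
property hierarchies and quantified axioms. `ontoview` checks each
table-derived relationship against that logic, suggests repairs where a
recorded relationship fails, and derives minimal, grouping-safe ontology
views over exactly the terms an application needs.

## The redundant graph

Most of the knowledge in an ontology is indirect: a podocyte is asserted to
be part of the glomerular visceral epithelium, and a chain of `part_of`
edges connects that epithelium to the kidney. `saturate()` materializes all
of this into a *redundant graph* — the least fixpoint of five rules over
the asserted edges:

* **R1** `subClassOf` transitivity;
* **R2** property hierarchy: `a r b` and `r ⊑ r'` entail `a r' b`
  (e.g. `bounding_layer_of ⊑ part_of`);
* **R3** declared transitive properties compose with themselves;
* **R4** subclass propagation: `a subClassOf b, b r c ⟹ a r c` and
  `a r b, b subClassOf c ⟹ a r c`, for every object property `r`;
* **R5** property chains: `a r1 b, b r2 c ⟹ a r3 c` for each declared
  chain `r1 ∘ r2 ⊑ r3`.

The rule set is deliberately restricted to what existential-restriction
graphs support: no inverse properties, no equivalence reasoning, no
cardinality, no classification of defined classes. R4 applies uniformly to
every object property; this is what makes `podocyte part_of kidney` fall
out of a mixed subsumption/partonomy chain. Evaluation is semi-naive (each
round joins the newest edges against the accumulated closure), terminates
on any input because the edge space is finite, and tolerates cycles.
Reflexive subsumption (`x subClassOf x`) is answered `TRUE` at query time
by `entails()` but never materialized, so closure counts stay meaningful.

```{r kidney}
rg <- saturate(builtin_fixture("kidney"))
glance(rg)
entails(rg, "CL:0000653", PART_OF, "UBERON:0002113")  # podocyte in kidney?
```

The test suite pins this engine to an independent naive
re-apply-all-rules-until-stable oracle on 25 seeded 50-term random
ontologies, and to hand-checkable entailments on the built-in fixtures.

## Table semantics

`parse_asctb()` accepts the `CATEGORY/index/FIELD` header convention,
skipping leading metadata rows, and `extract_triples()` applies the
standard interpretation of adjacency:

* adjacent filled AS cells (ascending index, *skipping blanks* so the most
  specific filled entry links onward) give `ccf_part_of` — or
  `ccf_branching_part_of` for vasculature tables — with the more specific
  term as subject;
* the first filled CT links to the *last* filled AS via `ccf_located_in`;
* adjacent CT cells give `ccf_is_a`, again more specific on the right;
* each B links to the last filled CT via `ccf_characterizes`.

Three of these are conventions the table format leaves open, fixed here
once: blank cells are skipped rather than breaking the chain; `ccf_is_a`
points from the right (more specific) cell type to the left, mirroring the
AS direction; and `ccf_located_in` targets only the last AS, matching the
graph renderings that accompany published tables. All are isolated in
`extract_triples()` should a deployment need the opposite convention.
Duplicate triples across rows merge with all source coordinates retained;
a term adjacent to itself produces a triple flagged `self_reference`
rather than vanishing; identifier cells that do not normalize to a CURIE
(including printed artifacts like `"CL: 1001131"`, whose internal
whitespace is stripped) are kept verbatim and surface later as
`unresolved_term`.

## The validation order

For each triple the validator walks an *ordered* candidate list for its
category pair and accepts the first relation the redundant graph entails:

| pair     | candidates, in order                                | reversed |
|----------|-----------------------------------------------------|----------|
| AS → AS  | `subClassOf`, `part_of`, `overlaps`, `connected_to` | —        |
| CT → AS  | `part_of`, `overlaps`                               | `has_part` (AS → CT) |
| CT → CT  | `subClassOf`, `develops_from`                       | —        |

The order matters: tables mix subsumption and parthood freely, and when
both hold the more informative subsumption is preferred. Reversed
`has_part` matches are reported as `valid_reversed`, never silently
rewritten, so the output edge direction is explicit. The lists live in a
`validation_config()` and can be loaded from YAML; `ccf_branching_part_of`
shares the AS→AS lists because no separate mapping is established for it.

When nothing matches, `suggest_fallback()` searches the hierarchy's own
term set for the *most precise enclosing term* the ontology supports: for
the first suggestion relation (default `part_of`; `subClassOf` for CT→CT)
with any entailed target, it returns the target minimal under the entailed
`part_of`/`subClassOf` order, ties broken by lexicographic CURIE so runs
are reproducible. A keratocyte recorded in the anterior stroma — a link
the ontology does not support, since keratocytes occupy the whole
substantia propria — is thus suggested `part_of` the cornea, the best
fit among the table's terms:

```{r cornea}
h <- extract_triples(builtin_fixture("cornea_rows"))
rep <- validate_hierarchy(h, saturate(builtin_fixture("cornea")),
                          run_date = "2025-01-01")
tidy(rep) |> select(subject_label, predicate, object_label, status,
                    suggested_object)
```

A genuinely generic cell type (the telocyte here) gets no suggestion: a
`part_of` link anywhere would be wrong, and the formally correct repair —
a `has_part` edge from the structure — is deliberately not emitted by
default because it changes the modeling of the table rather than repairing
a link (`check_pair()` exposes reversed candidates for callers who want it).

Biomarker `ccf_characterizes` triples cannot be tested against an
anatomy/cell ontology at all; they are carried through with status
`skipped` (a sixth status alongside `valid`, `valid_reversed`,
`suggested`, `invalid`, `unresolved_term`) so that status counts still
partition the triple count and the output ontology preserves them.

`compile_output_ontology()` assembles the deliverable: validated and
suggested logical edges stamped with `validation_status` and the
caller-supplied run date (never the wall clock), plus *every* original
triple as a non-logical annotation edge keyed by its bespoke `ccf_*`
predicate — the table graph is preserved verbatim without contaminating
logic-based queries.

## Minimal views and transitive reduction

`extract_subset()` links every ordered pair of requested terms by every
requested relation the closure entails — so terms connect even when no
direct edge exists in the source ontology — then simplifies twice. First,
on any single pair, a relation implied purely by a kept subproperty is
dropped (`part_of` goes if `bounding_layer_of` stays); `subClassOf` next
to `part_of` survives, as the two are logically independent. Second,
`transitive_reduce()` greedily deletes, in sorted (subject, relation,
object) order, any edge still entailed after re-saturating the remainder.

Using entailment as the reduction criterion — rather than per-relation
transitive reduction — means subproperty and chain interactions are
respected, at the price of one saturation per candidate edge; for the
view sizes this package targets (tens to low hundreds of terms) that is
cheap. The greedy order makes the result deterministic; it is one minimal
edge set among possibly several. The information-preservation guarantee —
saturating the reduced view, restricted to the term set and requested
relations, equals saturating the unreduced subset — is asserted on every
fixture in the test suite, as is grouping safety: descendant queries over
`part_of ∪ subClassOf` agree between the reduced view and the full
closure. No terms outside the requested set are ever injected.

```{r view}
v <- extract_subset(rg, rg$base$terms$id,
                    relations = c(SUBCLASS_OF, PART_OF, BOUNDING_LAYER_OF))
summarize_view(v)
```

`emit_table()` flattens an acyclic view back into table form, one row per
maximal root-to-leaf path, so domain experts can review implicit ontology
structure in the spreadsheet idiom they authored it in.

## Interchange formats

Ontologies travel as OBO Graphs JSON (`read_obograph()` /
`write_obograph()`): nodes with `id`/`lbl`, edges with `sub`/`pred`/`obj`,
`"is_a"` standing for `subClassOf`. Two dialect choices are worth knowing.
Validation metadata and annotation-edge provenance ride in edge-level
`meta.basicPropertyValues`, and the property schema (relation
declarations, transitivity, subproperty axioms, chains, labels) plus the
prefix map ride in graph-level `meta.basicPropertyValues`, because the
format has no native slot for either; both round-trip bit-identically.
Unknown predicates in third-party files are auto-declared as plain object
properties so real ontologies load; `strict = TRUE` turns that into an
error. All writers (obographs, DOT, CSV, edge TSV) sort their output, so
equal inputs produce byte-identical files — the determinism the test
suite asserts.

## What the random generator emulates — and what it does not

`random_ontology()` builds index-ordered DAGs: `subClassOf` and `part_of`
edges within each category point only from higher- to lower-index terms
(acyclic by construction, no detection needed), with defaults of 30 AS +
20 CT terms, edge density 0.05 per relation, and sparse extra
`bounding_layer_of`/`overlaps` edges (probability 0.02) to exercise the
subproperty machinery. Those sizes keep a full 25-seed oracle comparison
in the test suite under a minute while producing closures in the hundreds
of edges — large enough that rule interactions genuinely occur.

The generator emulates graph *shape*, not biology: it has no label
duplication, no unmapped identifiers, no ragged table rows, no
multi-organ sharing of cell types, and its densities are uniform rather
than the hub-heavy structure of real partonomies. Passing tests on random
fixtures therefore demonstrate logical correctness of the engine, not
robustness to the full messiness of production tables — that is what the
hand-built fixtures (generic-endothelium, cornea/keratocyte, stray
whitespace in identifiers) cover, each anchored to an error pattern
observed in real curation.

## Numerical and degenerate-input choices

* Saturation of an edgeless ontology is the empty closure; cyclic inputs
  are legal (mutual `part_of` edges entail each other) and terminate.
* `entails()` on undeclared terms warns and returns `FALSE`; during bulk
  validation the membership check runs first, so unmapped identifiers
  become `unresolved_term` outcomes, not warnings.
* Cycle detection (subproperty hierarchy, transitive-relation edge sets,
  table emission) reports the offending members by name.
* Ties anywhere a single representative must be chosen (fallback targets,
  greedy reduction order, writer output order) break by lexicographic
  CURIE.
* `run_date` is always injected by the caller, making reports and output
  ontologies reproducible byte for byte.

## Limitations

The reasoner is an existential-restriction materializer, not an OWL-DL
reasoner: equivalence, negation, cardinality, inverse properties and
domain/range inference are out of scope, as is consistency checking.
Validation covers AS/CT structure; biomarker links pass through
unvalidated. The package operates entirely on local ontology files —
there is no live triplestore querying — so results are only as current as
the ontology snapshot supplied.
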