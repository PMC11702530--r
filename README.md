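# ontoview

Validate expert-curated anatomy / cell-type hierarchies against reference
ontologies, and build simplified, grouping-safe ontology views.

## Why

Atlas projects collect expert knowledge in ASCT+B-style spreadsheets:
anatomical structures (AS) nested left-to-right within a row, cell types
(CT) attached to the most specific structure, biomarkers (B) attached to
cell types. Adjacency encodes *a* hierarchical relationship, but not which
one — and only subsumption (`subClassOf`) and parthood (`part_of`,
BFO:0000050, with subproperties such as `bounding_layer_of`) are safe for
grouping annotations by location. Relations like `overlaps` (RO:0002131)
or `connected_to` (RO:0002170) are not: if A overlaps B, an annotation to
A need not lie in B.

`ontoview` is for curators and ontology engineers who need to know, for
every recorded relationship, whether reference ontologies such as Uberon
and the Cell Ontology actually support it — and, where they do not, what
the best supported repair is.

## What it does

1. **Saturation.** `saturate()` materializes the *redundant graph*: the
   least fixpoint of `subClassOf` transitivity, property-hierarchy
   inference (`a r b, r ⊑ r' ⟹ a r' b`), transitive-property composition,
   subclass propagation (`a subClassOf b, b r c ⟹ a r c` and symmetrically),
   and property chains (`r1 ∘ r2 ⊑ r3`). Every indirect relationship
   becomes directly queryable with `entails()`.
2. **Table parsing.** `parse_asctb()` + `extract_triples()` turn a table
   into typed triples (`ccf_part_of`, `ccf_located_in`, `ccf_is_a`,
   `ccf_characterizes`) with source coordinates.
3. **Validation.** `validate_hierarchy()` tests each triple against an
   ordered candidate list per category pair (AS→AS: `subClassOf`,
   `part_of`, `overlaps`, `connected_to`; CT→AS: `part_of`, `overlaps`,
   then reversed `has_part`; CT→CT: `subClassOf`, `develops_from`) and,
   on failure, suggests the most precise enclosing term in the table that
   the ontology does support. `compile_output_ontology()` writes validated
   and suggested edges as logical axioms (stamped with validation status
   and date) and preserves every original table triple as a non-logical
   annotation edge.
4. **Views.** `extract_subset()` + `transitive_reduce()` produce a minimal
   ontology over exactly the terms you request, linking them through the
   closure even when not directly connected, then deleting every edge that
   is still entailed without it. `summarize_view()` reports terms /
   relationships / relation types; `emit_table()` flattens a view back to
   table form for expert review.
5. **Reports.** `emit_dot()` (Graphviz; unsupported edges red, suggestions
   green, AS nodes red, CT nodes blue) and `emit_validation_csv()`.

Everything is offline: ontologies load from OBO Graphs JSON or edge TSV,
and built-in fixtures plus a seeded random-ontology generator make every
stage testable without downloads.

## Worked example

```r
library(ontoview)

rg <- saturate(builtin_fixture("kidney"))
glance(rg)
#> # A tibble: 1 × 4
#>   n_terms n_closure_edges n_asserted n_inferred
#>     <int>           <int>      <int>      <int>
#> 1       9              20          8         12

entails(rg, "CL:0000653", PART_OF, "UBERON:0002113")   # podocyte in kidney?
#> [1] TRUE
```

Eight asserted edges (a podocyte→epithelial-cell→cell classification
chain, a podocyte→…→kidney partonomy chain, and a `bounding_layer_of`
edge for the kidney capsule) saturate to 20: the 12 inferred edges include
`podocyte part_of kidney` (mixed subsumption/partonomy chain) and
`kidney capsule part_of kidney` (subproperty rule).

```r
h   <- extract_triples(builtin_fixture("cornea_rows"))
rep <- validate_hierarchy(h, saturate(builtin_fixture("cornea")),
                          run_date = "2025-01-01")
tidy(rep)[, c("subject_label", "predicate", "object_label", "status",
              "suggested_object")]
#> # A tibble: 3 × 5
#>   subject_label             predicate      object_label  status suggested_object
#>   <chr>                     <chr>          <chr>         <chr>  <chr>
#> 1 keratocyte                ccf_located_in anterior str… sugge… UBERON:0000964
#> 2 anterior stroma of cornea ccf_part_of    cornea        valid  <NA>
#> 3 telocyte                  ccf_located_in anterior str… inval… <NA>
```

The keratocyte/anterior-stroma link is unsupported (keratocytes occupy the
whole substantia propria), so the validator suggests `part_of` the cornea
(UBERON:0000964) — the most precise enclosing structure among the table's
own terms. The telocyte, a generic cell type, gets no suggestion at all.

```r
v <- extract_subset(rg, rg$base$terms$id,
                    relations = c(SUBCLASS_OF, PART_OF, BOUNDING_LAYER_OF))
summarize_view(v)
#> # A tibble: 1 × 3
#>   n_terms n_relationships n_relation_types
#>     <int>           <int>            <int>
#> 1       9               8                3
```

The 20-edge closure reduces back to a minimal 8-edge view whose saturation
restricted to those terms is provably unchanged.

A thin CLI over the same functions ships in `inst/scripts/ontoview.R`
(`saturate`, `triples`, `validate`, `extract`, `stats`, `fixture`
subcommands).

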