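#' Construct an ontology view
#'
#' A view is a reduced, application-specific ontology: a term subset with
#' logical edges (safe for reasoning and grouping) kept separate from
#' annotation edges (provenance-only, e.g. the original table relations).
#' The two edge sets are disjoint and all endpoints must be declared terms.
#'
#' @param terms A term tibble ([term_tbl()]).
#' @param logical_edges Edge tibble with provenance `"asserted"`.
#' @param annotation_edges Edge tibble with provenance `"annotation"`.
#' @param schema A [property_schema()].
#' @param prefixes A [prefix_map()].
#' @param id Identifier string.
#' @return A `view_ontology`.
#' @export
view_ontology <- function(terms = term_tbl(), logical_edges = edge_tbl(),
                          annotation_edges = edge_tbl(),
                          schema = default_schema(),
                          prefixes = default_prefixes(), id = "view") {
  terms <- tibble::as_tibble(terms)
  if (!"label" %in% names(terms)) terms$label <- ""
  if (!"category" %in% names(terms)) terms$category <- "none"
  terms <- dplyr::arrange(dplyr::distinct(terms[c("id", "label", "category")]),
                          .data$id)
  logical_edges <- sort_edges(dplyr::distinct(complete_edge_tbl(logical_edges)))
  annotation_edges <- sort_edges(dplyr::distinct(complete_edge_tbl(annotation_edges)))
  logical_edges$provenance <- "asserted"
  annotation_edges$provenance <- "annotation"
  bad <- setdiff(c(logical_edges$subject, logical_edges$object,
                   annotation_edges$subject, annotation_edges$object),
                 terms$id)
  if (length(bad) > 0L) {
    rlang::abort(paste0("view edge references undeclared term(s): ",
                        paste(sort(bad), collapse = ", ")))
  }
  both <- dplyr::inner_join(
    logical_edges[c("subject", "relation", "object")],
    annotation_edges[c("subject", "relation", "object")],
    by = c("subject", "relation", "object"))
  if (nrow(both) > 0L) {
    rlang::abort("logical and annotation edge sets must be disjoint")
  }
  structure(list(terms = terms, logical_edges = logical_edges,
                 annotation_edges = annotation_edges, schema = schema,
                 prefixes = prefixes, id = id),
            class = "view_ontology")
}

#' @export
print.view_ontology <- function(x, ...) {
  cat("<view_ontology> ", x$id, ": ", nrow(x$terms), " terms, ",
      nrow(x$logical_edges), " logical edges, ",
      nrow(x$annotation_edges), " annotation edges\n", sep = "")
  invisible(x)
}

#' Tidy a view into its combined edge table
#'
#' @param x A `view_ontology`.
#' @param ... Unused.
#' @return Edge tibble (logical edges, then annotation edges).
#' @method tidy view_ontology
#' @export
tidy.view_ontology <- function(x, ...) {
  dplyr::bind_rows(x$logical_edges, x$annotation_edges)
}

#' Convert a view to a plain ontology (for serialization or re-saturation)
#'
#' @param x A `view_ontology`.
#' @return An [ontology()] carrying both edge sets.
#' @export
as_ontology <- function(x) {
  stopifnot(inherits(x, "view_ontology"))
  ontology(terms = x$terms,
           edges = dplyr::bind_rows(x$logical_edges, x$annotation_edges),
           schema = x$schema, prefixes = x$prefixes, id = x$id)
}

#' Extract a minimal view over a term subset
#'
#' For every ordered pair of distinct terms in `term_set`, each requested
#' relation entailed by the closure yields a candidate edge — so terms are
#' linked even when not directly connected in the source ontology. Two
#' simplifications then apply: (i) on a given pair, a relation implied purely
#' by a more specific kept relation via the subproperty hierarchy is dropped
#' (keep minimal relations only; independent relations such as `subClassOf`
#' alongside `part_of` are both kept); (ii) the surviving edges pass through
#' [transitive_reduce()]. No terms outside `term_set` are introduced.
#'
#' @param graph A `redundant_graph` from [saturate()].
#' @param term_set Character vector of CURIEs (non-empty).
#' @param relations Ordered character vector of requested relations; must be
#'   declared in the schema.
#' @param reduce If `FALSE`, skip the transitive reduction step.
#' @return A `view_ontology`.
#' @export
extract_subset <- function(graph, term_set,
                           relations = c(SUBCLASS_OF, PART_OF),
                           reduce = TRUE) {
  stopifnot(inherits(graph, "redundant_graph"))
  if (length(term_set) == 0L) rlang::abort("term_set must be non-empty")
  schema <- graph$base$schema
  undeclared <- setdiff(relations, schema$relations)
  if (length(undeclared) > 0L) {
    rlang::abort(paste0("requested relation(s) not declared: ",
                        paste(undeclared, collapse = ", ")))
  }
  term_set <- unique(term_set)
  cl <- graph$closure
  edges <- cl[cl$subject %in% term_set & cl$object %in% term_set &
                cl$relation %in% relations & cl$subject != cl$object,
              c("subject", "relation", "object")]
  edges <- dplyr::distinct(edges)

  # keep only minimal relations per pair under the subproperty order
  sup <- superproperty_closure(schema)
  if (nrow(edges) > 0L) {
    keep <- vapply(seq_len(nrow(edges)), function(i) {
      same_pair <- edges$subject == edges$subject[i] &
        edges$object == edges$object[i] & edges$relation != edges$relation[i]
      others <- edges$relation[same_pair]
      !any(vapply(others, function(r2)
        edges$relation[i] %in% setdiff(sup[[r2]], r2), logical(1)))
    }, logical(1))
    edges <- edges[keep, ]
  }

  edges <- edge_tbl(subject = edges$subject, relation = edges$relation,
                    object = edges$object, provenance = "asserted")
  if (reduce) {
    edges <- transitive_reduce(edges, schema, term_set)
  }

  terms <- tibble::tibble(id = term_set) |>
    dplyr::left_join(graph$base$terms, by = "id") |>
    dplyr::mutate(label = .data$label %|% "",
                  category = .data$category %|% "none")
  view_ontology(terms = terms, logical_edges = edges,
                annotation_edges = edge_tbl(), schema = schema,
                prefixes = graph$base$prefixes,
                id = paste0(graph$base$id, "_view"))
}

#' Entailment-preserving transitive reduction
#'
#' Greedily removes, in deterministic sorted order (subject, relation,
#' object), any edge still entailed after saturating the remaining edges
#' under the schema — so plain transitive shortcuts, subproperty-implied
#' duplicates and chain consequences are all eliminated while every original
#' entailment among the terms is preserved. The result is one minimal edge
#' set among possibly several; the fixed order makes it reproducible.
#'
#' Edges of each transitive relation (and `subClassOf`) must be acyclic; a
#' cycle is an error naming its members.
#'
#' @param edges An edge tibble.
#' @param schema A [property_schema()].
#' @param term_set Terms over which entailment must be preserved (defaults to
#'   the edge endpoints).
#' @return The surviving edge tibble.
#' @export
transitive_reduce <- function(edges, schema,
                              term_set = unique(c(edges$subject, edges$object))) {
  edges <- sort_edges(dplyr::distinct(complete_edge_tbl(edges)))
  for (r in c(SUBCLASS_OF, schema$transitive)) {
    er <- edges[edges$relation == r, ]
    if (nrow(er) > 0L) {
      check_acyclic_pairs(er$subject, er$object,
                          what = paste0("edges of transitive relation ", r))
    }
  }
  still_entailed <- function(remaining, e) {
    onto <- ontology(terms = term_tbl(id = unique(c(term_set,
                                                    remaining$subject,
                                                    remaining$object,
                                                    e$subject, e$object))),
                     edges = remaining, schema = schema, id = "reduce_probe")
    rg <- saturate(onto)
    cl <- rg$closure
    any(cl$subject == e$subject & cl$relation == e$relation &
          cl$object == e$object)
  }
  i <- 1L
  while (i <= nrow(edges)) {
    e <- edges[i, ]
    remaining <- edges[-i, ]
    if (nrow(remaining) > 0L && still_entailed(remaining, e)) {
      edges <- remaining
    } else {
      i <- i + 1L
    }
  }
  edges
}

#' Summary statistics of a view
#'
#' Counts terms, logical relationships and distinct relation types; the
#' headline numbers quoted for simplified atlas ontologies. Annotation edges
#' are excluded.
#'
#' @param view A `view_ontology`.
#' @return A one-row tibble with `n_terms`, `n_relationships`,
#'   `n_relation_types`.
#' @export
summarize_view <- function(view) {
  stopifnot(inherits(view, "view_ontology"))
  tibble::tibble(n_terms = nrow(view$terms),
                 n_relationships = nrow(view$logical_edges),
                 n_relation_types = dplyr::n_distinct(view$logical_edges$relation))
}

#' @rdname summarize_view
#' @param x A `view_ontology`.
#' @param ... Unused.
#' @method glance view_ontology
#' @export
glance.view_ontology <- function(x, ...) summarize_view(x)
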