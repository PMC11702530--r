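meta_cols <- c("validation_status", "validation_date", "source_relation")

#' Build an edge table
#'
#' Edges are kept as a tibble with one row per (subject, relation, object,
#' provenance) and string metadata columns carrying validation status/date
#' and, for annotation edges, the original table predicate. Annotation edges
#' never participate in reasoning.
#'
#' @param subject,relation,object Character vectors (recycled to a common
#'   length) of CURIEs; `relation` may also be the token `subClassOf`.
#' @param provenance One of `"asserted"`, `"inferred"`, `"annotation"`.
#' @param validation_status,validation_date,source_relation Optional string
#'   metadata.
#' @return A tibble with the canonical edge columns.
#' @export
edge_tbl <- function(subject = character(), relation = character(),
                     object = character(), provenance = "asserted",
                     validation_status = NA_character_,
                     validation_date = NA_character_,
                     source_relation = NA_character_) {
  tibble::tibble(subject = as.character(subject),
                 relation = as.character(relation),
                 object = as.character(object),
                 provenance = as.character(provenance),
                 validation_status = as.character(validation_status),
                 validation_date = as.character(validation_date),
                 source_relation = as.character(source_relation))
}

empty_edge_tbl <- function() edge_tbl()

complete_edge_tbl <- function(edges) {
  if (is.null(edges)) return(empty_edge_tbl())
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0L && ncol(edges) == 0L) return(empty_edge_tbl())
  if (!"provenance" %in% names(edges)) edges$provenance <- "asserted"
  for (mc in meta_cols) if (!mc %in% names(edges)) edges[[mc]] <- NA_character_
  edges <- edges[c("subject", "relation", "object", "provenance", meta_cols)]
  edges$provenance[is.na(edges$provenance)] <- "asserted"
  edges
}

sort_edges <- function(edges) {
  dplyr::arrange(edges, .data$subject, .data$relation, .data$object,
                 .data$provenance)
}

#' Build a term table
#'
#' @param id Character vector of CURIEs (or unresolvable raw identifiers,
#'   which downstream validation reports as unresolved).
#' @param label Character vector of labels; may be empty strings. Labels need
#'   not be unique — distinct structures may share a name and are told apart
#'   by their identifiers.
#' @param category Optional category tag per term: `"AS"` (anatomical
#'   structure), `"CT"` (cell type), `"B"` (biomarker) or `"none"`.
#' @return A tibble with columns `id`, `label`, `category`.
#' @export
term_tbl <- function(id = character(), label = "", category = "none") {
  tibble::tibble(id = as.character(id), label = as.character(label),
                 category = as.character(category))
}

#' Construct an ontology
#'
#' An ontology is a set of terms, a set of asserted edges among them, the
#' [property_schema()] declaring the relations in play, and a [prefix_map()].
#' Every edge endpoint must be a declared term and every edge relation a
#' declared relation (annotation edges may instead use a bespoke table
#' predicate such as `ccf_part_of`).
#'
#' @param terms A tibble from [term_tbl()].
#' @param edges A tibble from [edge_tbl()]; provenance must be `"asserted"`
#'   (or `"annotation"` for non-logical edges).
#' @param schema A [property_schema()].
#' @param prefixes A [prefix_map()].
#' @param id Optional identifier string for the ontology.
#' @return An `ontology` object.
#' @export
ontology <- function(terms = term_tbl(), edges = edge_tbl(),
                     schema = default_schema(),
                     prefixes = default_prefixes(),
                     id = "ontology") {
  terms <- tibble::as_tibble(terms)
  if (!"label" %in% names(terms)) terms$label <- ""
  if (!"category" %in% names(terms)) terms$category <- "none"
  terms <- dplyr::arrange(dplyr::distinct(terms[c("id", "label", "category")]),
                          .data$id)
  if (anyDuplicated(terms$id) > 0L) {
    rlang::abort("term ids must be unique within an ontology")
  }
  edges <- sort_edges(dplyr::distinct(complete_edge_tbl(edges)))
  if (any(!edges$provenance %in% c("asserted", "annotation"))) {
    rlang::abort("ontology edges must have provenance 'asserted' or 'annotation'")
  }
  bad_ep <- setdiff(c(edges$subject, edges$object), terms$id)
  if (length(bad_ep) > 0L) {
    rlang::abort(paste0("edge references undeclared term(s): ",
                        paste(sort(bad_ep), collapse = ", ")))
  }
  logical_rel <- edges$relation[edges$provenance != "annotation"]
  bad_rel <- setdiff(logical_rel, schema$relations)
  if (length(bad_rel) > 0L) {
    rlang::abort(paste0("edge uses undeclared relation(s): ",
                        paste(sort(bad_rel), collapse = ", ")))
  }
  structure(list(terms = terms, edges = edges, schema = schema,
                 prefixes = prefixes, id = id),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", x$id, ": ", nrow(x$terms), " terms, ",
      sum(x$edges$provenance == "asserted"), " asserted edges\n", sep = "")
  invisible(x)
}

#' Tidy an ontology into its edge table
#'
#' @param x An [ontology()].
#' @param ... Unused.
#' @return The edge tibble.
#' @method tidy ontology
#' @export
tidy.ontology <- function(x, ...) x$edges

#' One-row summary of an ontology
#'
#' @param x An [ontology()].
#' @param ... Unused.
#' @return A one-row tibble with term and edge counts.
#' @method glance ontology
#' @export
glance.ontology <- function(x, ...) {
  tibble::tibble(id = x$id, n_terms = nrow(x$terms),
                 n_edges = nrow(x$edges),
                 n_relations = dplyr::n_distinct(x$edges$relation))
}

term_label <- function(onto, ids) {
  lab <- stats::setNames(onto$terms$label, onto$terms$id)[ids]
  ifelse(is.na(lab), "", lab)
}
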