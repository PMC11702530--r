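#' Validation rule configuration
#'
#' For each category pair the validator tries an ordered list of candidate
#' relations and accepts the first one entailed by the redundant graph; if
#' none holds, `reversed_rules` are tried with subject and object swapped
#' (e.g. `has_part` from the anatomical structure to the cell type); if that
#' also fails, `suggestion_relations` drive the most-specific fallback
#' search. Defaults follow the standard validation order:
#'
#' * AS to AS — `subClassOf`, `part_of`, `overlaps`, `connected_to`;
#' * CT to AS — `part_of`, `overlaps`; reversed: `has_part`;
#' * CT to CT — `subClassOf`, `develops_from`.
#'
#' @param rules Named list (`AS_AS`, `CT_AS`, `CT_CT`) of ordered relation
#'   vectors.
#' @param reversed_rules Named list of ordered relation vectors tested with
#'   subject/object swapped.
#' @param suggestion_relations Named list of ordered relation vectors for the
#'   fallback search.
#' @return A `validation_config` object.
#' @export
validation_config <- function(rules = NULL, reversed_rules = NULL,
                              suggestion_relations = NULL) {
  rules <- rules %||% list(
    AS_AS = c(SUBCLASS_OF, PART_OF, OVERLAPS, CONNECTED_TO),
    CT_AS = c(PART_OF, OVERLAPS),
    CT_CT = c(SUBCLASS_OF, DEVELOPS_FROM))
  reversed_rules <- reversed_rules %||% list(CT_AS = HAS_PART)
  suggestion_relations <- suggestion_relations %||% list(
    AS_AS = PART_OF, CT_AS = PART_OF, CT_CT = SUBCLASS_OF)
  for (cp in c("AS_AS", "CT_AS", "CT_CT")) {
    if (length(rules[[cp]]) == 0L) {
      rlang::abort(paste0("rules for ", cp, " must be non-empty"))
    }
  }
  structure(list(rules = rules, reversed_rules = reversed_rules,
                 suggestion_relations = suggestion_relations),
            class = "validation_config")
}

#' Read a validation rule configuration from YAML
#'
#' Expected keys: `rules`, `reversed_rules`, `suggestion_relations`, each a
#' mapping from category pair (`AS_AS`, `CT_AS`, `CT_CT`) to an ordered list
#' of relation CURIEs (or `subClassOf`). Missing keys fall back to the
#' defaults of [validation_config()].
#'
#' @param path YAML file path.
#' @return A `validation_config`.
#' @export
read_validation_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_rel_list <- function(x) {
    if (is.null(x)) return(NULL)
    lapply(x, function(v) as.character(unlist(v)))
  }
  defaults <- validation_config()
  validation_config(
    rules = utils::modifyList(defaults$rules, as_rel_list(y$rules) %||% list()),
    reversed_rules = utils::modifyList(defaults$reversed_rules,
                                       as_rel_list(y$reversed_rules) %||% list()),
    suggestion_relations = utils::modifyList(defaults$suggestion_relations,
                                             as_rel_list(y$suggestion_relations) %||% list()))
}

#' Test a subject/object pair against an ordered candidate list
#'
#' Returns the first candidate relation (in list order) entailed between
#' subject and object; failing that, the first reversed candidate entailed
#' between object and subject, flagged `"reversed"`; otherwise `NULL`.
#' Undeclared terms simply fail to entail.
#'
#' @param graph A `redundant_graph` from [saturate()].
#' @param subject,object Term CURIEs.
#' @param candidates Ordered character vector of candidate relations.
#' @param reversed_candidates Ordered character vector tried with the pair
#'   swapped (may be empty).
#' @return `NULL`, or a list with elements `relation` and `direction`
#'   (`"forward"` or `"reversed"`).
#' @export
check_pair <- function(graph, subject, object, candidates,
                       reversed_candidates = character()) {
  if (length(candidates) == 0L) rlang::abort("candidate list must be non-empty")
  quiet_entails <- function(...) {
    withCallingHandlers(entails(...),
                        ontoview_undeclared = function(w) invokeRestart("muffleWarning"))
  }
  for (r in candidates) {
    if (quiet_entails(graph, subject, r, object)) {
      return(list(relation = r, direction = "forward"))
    }
  }
  for (r in reversed_candidates) {
    if (quiet_entails(graph, object, r, subject)) {
      return(list(relation = r, direction = "reversed"))
    }
  }
  NULL
}

#' Suggest the most specific valid fallback relationship
#'
#' When a recorded relationship does not validate, search the hierarchy's own
#' term set for the most precise enclosing term the redundant graph supports:
#' for the first relation `r` in `suggestion_relations` with any entailed
#' target, return the target that is minimal under the entailed
#' `part_of`/`subClassOf` order (no other candidate target lies below it),
#' ties broken by lexicographic CURIE. Returns `NULL` when no relation yields
#' a target.
#'
#' @param graph A `redundant_graph`.
#' @param subject Term CURIE (member of `term_set`).
#' @param term_set Character vector of candidate target CURIEs.
#' @param suggestion_relations Ordered character vector of relations.
#' @return `NULL`, or a list with elements `relation` and `object`.
#' @export
suggest_fallback <- function(graph, subject, term_set,
                             suggestion_relations = PART_OF) {
  quiet_entails <- function(...) {
    withCallingHandlers(entails(...),
                        ontoview_undeclared = function(w) invokeRestart("muffleWarning"))
  }
  term_set <- setdiff(unique(term_set), subject)
  for (r in suggestion_relations) {
    hits <- term_set[vapply(term_set, function(o) quiet_entails(graph, subject, r, o),
                            logical(1))]
    if (length(hits) == 0L) next
    below <- function(o) {
      any(vapply(setdiff(hits, o), function(o2) {
        quiet_entails(graph, o2, PART_OF, o) ||
          quiet_entails(graph, o2, SUBCLASS_OF, o)
      }, logical(1)))
    }
    minimal <- hits[!vapply(hits, below, logical(1))]
    if (length(minimal) == 0L) minimal <- hits  # mutually-entailing cycle
    return(list(relation = r, object = sort(minimal)[[1]]))
  }
  NULL
}

#' Validate a term hierarchy against a redundant graph
#'
#' Each triple is tested with [check_pair()] using the candidate lists for
#' its category pair (`ccf_branching_part_of` shares the AS-to-AS lists with
#' `ccf_part_of`); failures fall back to [suggest_fallback()] over the
#' hierarchy's resolved term set. Triples whose subject or object is missing
#' from the graph's terms (unmapped or mistyped identifiers) get status
#' `unresolved_term`; biomarker `ccf_characterizes` triples are not
#' validatable against an anatomy/cell ontology and get status `skipped`.
#' Outcomes keep the input triple order.
#'
#' @param hierarchy A `term_hierarchy` from [extract_triples()].
#' @param graph A `redundant_graph` from [saturate()].
#' @param config A [validation_config()].
#' @param run_date ISO date string recorded on the report (injected, never
#'   read from the clock, so runs are reproducible).
#' @return A `validation_report`: an outcome tibble plus status counts.
#' @export
validate_hierarchy <- function(hierarchy, graph,
                               config = validation_config(),
                               run_date = "1970-01-01") {
  stopifnot(inherits(hierarchy, "term_hierarchy"),
            inherits(graph, "redundant_graph"))
  graph_terms <- graph$base$terms$id
  term_set <- hierarchy$terms$id[hierarchy$terms$resolved]

  outcomes <- purrr::pmap_dfr(hierarchy$triples, function(subject, subject_label,
                                                          predicate, object,
                                                          object_label,
                                                          category_pair,
                                                          self_reference, sources) {
    out <- tibble::tibble(
      subject = subject, subject_label = subject_label, predicate = predicate,
      object = object, object_label = object_label,
      category_pair = category_pair, status = NA_character_,
      matched_relation = NA_character_, direction = NA_character_,
      suggested_relation = NA_character_, suggested_object = NA_character_,
      notes = "", sources = list(sources))
    if (predicate == "ccf_characterizes") {
      out$status <- "skipped"
      out$notes <- "not validated"
      return(out)
    }
    if (!subject %in% graph_terms || !object %in% graph_terms) {
      out$status <- "unresolved_term"
      missing <- c(subject, object)[!c(subject, object) %in% graph_terms]
      out$notes <- paste0("not in ontology: ", paste(missing, collapse = ", "))
      return(out)
    }
    cp <- category_pair
    hit <- check_pair(graph, subject, object,
                      candidates = config$rules[[cp]],
                      reversed_candidates = config$reversed_rules[[cp]] %||% character())
    if (!is.null(hit)) {
      out$status <- if (hit$direction == "forward") "valid" else "valid_reversed"
      out$matched_relation <- hit$relation
      out$direction <- hit$direction
      return(out)
    }
    sug <- suggest_fallback(graph, subject, term_set,
                            config$suggestion_relations[[cp]] %||% character())
    if (!is.null(sug)) {
      out$status <- "suggested"
      out$suggested_relation <- sug$relation
      out$suggested_object <- sug$object
      return(out)
    }
    out$status <- "invalid"
    out
  })
  if (nrow(hierarchy$triples) == 0L) {
    outcomes <- tibble::tibble(
      subject = character(), subject_label = character(),
      predicate = character(), object = character(),
      object_label = character(), category_pair = character(),
      status = character(), matched_relation = character(),
      direction = character(), suggested_relation = character(),
      suggested_object = character(), notes = character(), sources = list())
  }

  statuses <- c("valid", "valid_reversed", "suggested", "invalid",
                "unresolved_term", "skipped")
  counts <- stats::setNames(
    vapply(statuses, function(s) sum(outcomes$status == s), integer(1)),
    statuses)

  structure(list(outcomes = outcomes, counts = counts,
                 table_id = hierarchy$table_id,
                 ontology_id = graph$base$id, run_date = run_date),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$table_id, " vs ", x$ontology_id, " (",
      x$run_date, ")\n", sep = "")
  for (s in names(x$counts)) {
    if (x$counts[[s]] > 0L) cat("  ", s, ": ", x$counts[[s]], "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a validation report into its outcome table
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The outcome tibble, one row per triple.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$outcomes

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A one-row tibble with one column per status count.
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(table_id = x$table_id,
                                  ontology_id = x$ontology_id,
                                  n_triples = nrow(x$outcomes)),
                   tibble::as_tibble(as.list(x$counts)))
}

#' Assemble the annotated output ontology for a validation run
#'
#' The output view contains (i) one logical edge per `valid`/`valid_reversed`
#' outcome, using the matched relation in its matched direction, annotated
#' `validation_status = "validated"` with the run date; (ii) one logical edge
#' per suggestion, annotated `"suggested"`; and (iii) every original triple
#' as a non-logical annotation edge carrying its bespoke table predicate in
#' `source_relation`, so the original table graph is preserved without
#' interfering with logic-based queries. Terms are restricted to the
#' hierarchy's terms. Invalid and unresolved triples contribute no logical
#' edge.
#'
#' @param report A `validation_report` produced from `hierarchy`.
#' @param hierarchy The `term_hierarchy` that was validated.
#' @param graph The `redundant_graph` used (supplies schema and labels).
#' @param run_date ISO date string stamped on validated/suggested edges.
#' @return A `view_ontology`.
#' @export
compile_output_ontology <- function(report, hierarchy, graph,
                                    run_date = report$run_date) {
  stopifnot(inherits(report, "validation_report"),
            inherits(hierarchy, "term_hierarchy"))
  key <- function(tb) paste(tb$subject, tb$predicate, tb$object)
  if (!setequal(key(report$outcomes), key(hierarchy$triples))) {
    rlang::abort("report does not match hierarchy: triple sets differ")
  }

  oc <- report$outcomes
  fwd <- oc[!is.na(oc$status) & oc$status == "valid", ]
  rev <- oc[oc$status == "valid_reversed", ]
  sug <- oc[oc$status == "suggested", ]
  logical_edges <- dplyr::bind_rows(
    edge_tbl(subject = fwd$subject, relation = fwd$matched_relation,
             object = fwd$object, provenance = "asserted",
             validation_status = "validated", validation_date = run_date),
    edge_tbl(subject = rev$object, relation = rev$matched_relation,
             object = rev$subject, provenance = "asserted",
             validation_status = "validated", validation_date = run_date),
    edge_tbl(subject = sug$subject, relation = sug$suggested_relation,
             object = sug$suggested_object, provenance = "asserted",
             validation_status = "suggested", validation_date = run_date))
  logical_edges <- dplyr::distinct(
    logical_edges, .data$subject, .data$relation, .data$object,
    .keep_all = TRUE)

  tr <- hierarchy$triples
  annotation_edges <- edge_tbl(
    subject = tr$subject, relation = tr$predicate, object = tr$object,
    provenance = "annotation", source_relation = tr$predicate)

  terms <- tibble::tibble(id = hierarchy$terms$id,
                          label = hierarchy$terms$label,
                          category = hierarchy$terms$category)

  view_ontology(terms = terms, logical_edges = logical_edges,
                annotation_edges = annotation_edges,
                schema = graph$base$schema, prefixes = hierarchy$prefixes,
                id = paste0(report$table_id, "_validated"))
}
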