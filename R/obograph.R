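#' Read an OBO Graphs JSON document
#'
#' Parses the nodes/edges dialect of OBO Graphs JSON into an [ontology()].
#' Node IRIs are contracted to CURIEs via the prefix map; the predicate
#' `"is_a"` maps to the reserved [SUBCLASS_OF] token. Edge-level
#' `meta.basicPropertyValues` entries populate provenance and the
#' validation metadata columns; predicates without a colon (the bespoke
#' `ccf_*` table relations) pass through untouched on annotation edges.
#'
#' Property-schema facts (relation declarations, transitivity, subproperty
#' axioms, chains, relation labels) and the prefix map are stored as
#' graph-level `meta.basicPropertyValues` entries — OBO Graphs JSON has no
#' native slot for them — so a written ontology reconstructs exactly.
#' Documents without such entries fall back to `prefixes`/an empty schema,
#' and predicates not yet declared are auto-declared as plain
#' (non-transitive) object properties unless `strict = TRUE`.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @param prefixes Fallback [prefix_map()] when the document declares none.
#' @param strict If `TRUE`, an undeclared predicate is an error instead of
#'   being auto-declared.
#' @return An [ontology()].
#' @export
read_obograph <- function(source, prefixes = default_prefixes(),
                          strict = FALSE) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  if (is.null(doc$graphs) || length(doc$graphs) == 0L) {
    rlang::abort("obograph document has no graphs")
  }
  g <- doc$graphs[[1]]

  gm <- bpv_pairs(g$meta)
  if (any(gm$pred == "prefix")) {
    parts <- stringr::str_split_fixed(gm$val[gm$pred == "prefix"], " ", 2)
    prefixes <- prefix_map(stats::setNames(parts[, 2], parts[, 1]))
  }

  rels <- gm$val[gm$pred == "relation"]
  transitive <- gm$val[gm$pred == "transitive"]
  spo <- stringr::str_split_fixed(gm$val[gm$pred == "subPropertyOf"], " ", 2)
  chains <- stringr::str_split_fixed(gm$val[gm$pred == "chain"], " ", 3)
  labp <- stringr::str_split_fixed(gm$val[gm$pred == "relationLabel"], " ", 2)
  labels <- if (nrow(labp) > 0L) stats::setNames(labp[, 2], labp[, 1]) else character()

  nodes <- purrr::map_dfr(g$nodes, function(n) {
    nm <- bpv_pairs(n$meta)
    cat_val <- nm$val[nm$pred == "category"]
    term_tbl(id = contract_iri(n$id, prefixes),
             label = n$lbl %||% "",
             category = if (length(cat_val) > 0L) cat_val[[1]] else "none")
  })
  if (is.null(g$nodes) || length(g$nodes) == 0L) nodes <- term_tbl()

  edges <- purrr::map_dfr(g$edges, function(e) {
    em <- bpv_pairs(e$meta)
    pick <- function(k, default = NA_character_) {
      v <- em$val[em$pred == k]
      if (length(v) > 0L) v[[1]] else default
    }
    pred <- if (identical(e$pred, "is_a")) SUBCLASS_OF else contract_iri(e$pred, prefixes)
    edge_tbl(subject = contract_iri(e$sub, prefixes),
             relation = pred,
             object = contract_iri(e$obj, prefixes),
             provenance = pick("provenance", "asserted"),
             validation_status = pick("validation_status"),
             validation_date = pick("validation_date"),
             source_relation = pick("source_relation"))
  })
  if (is.null(g$edges) || length(g$edges) == 0L) edges <- edge_tbl()

  schema <- property_schema(
    relations = rels, transitive = transitive,
    sub_property_of = if (nrow(spo) > 0L)
      tibble::tibble(child = spo[, 1], parent = spo[, 2]) else NULL,
    chains = if (nrow(chains) > 0L)
      tibble::tibble(r1 = chains[, 1], r2 = chains[, 2], r3 = chains[, 3]) else NULL,
    labels = labels)

  logical_rels <- unique(edges$relation[edges$provenance != "annotation"])
  unknown <- setdiff(logical_rels, schema$relations)
  if (length(unknown) > 0L) {
    if (strict) {
      rlang::abort(paste0("undeclared predicate(s) in strict mode: ",
                          paste(sort(unknown), collapse = ", ")))
    }
    schema <- property_schema(
      relations = c(schema$relations, unknown),
      transitive = schema$transitive,
      sub_property_of = schema$sub_property_of,
      chains = schema$chains,
      labels = schema$labels)
  }

  ontology(terms = nodes, edges = edges, schema = schema, prefixes = prefixes,
           id = g$id %||% "ontology")
}

bpv_pairs <- function(meta) {
  if (is.null(meta) || is.null(meta$basicPropertyValues)) {
    return(tibble::tibble(pred = character(), val = character()))
  }
  purrr::map_dfr(meta$basicPropertyValues, function(p) {
    tibble::tibble(pred = as.character(p$pred), val = as.character(p$val))
  })
}

#' Write an ontology or view to OBO Graphs JSON
#'
#' Deterministic: nodes and edges are sorted by CURIE (then relation), so two
#' writes of equal ontologies are byte-identical. Validation metadata and, for
#' annotation edges, the original table predicate are carried as edge-level
#' `meta.basicPropertyValues`; the property schema and prefix map are carried
#' at graph level (see [read_obograph()] for the dialect).
#'
#' @param onto An [ontology()] or a `view_ontology`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return The JSON text, invisibly when written to `path`.
#' @export
write_obograph <- function(onto, path = NULL) {
  if (inherits(onto, "view_ontology")) onto <- as_ontology(onto)
  stopifnot(inherits(onto, "ontology"))
  prefixes <- onto$prefixes
  schema <- onto$schema
  terms <- dplyr::arrange(onto$terms, .data$id)
  edges <- sort_edges(onto$edges)

  gmeta <- c(
    lapply(names(prefixes), function(p) bpv("prefix", paste(p, prefixes[[p]]))),
    lapply(setdiff(schema$relations, SUBCLASS_OF), function(r) bpv("relation", r)),
    lapply(schema$transitive, function(r) bpv("transitive", r)),
    purrr::pmap(schema$sub_property_of, function(child, parent)
      bpv("subPropertyOf", paste(child, parent))),
    purrr::pmap(schema$chains, function(r1, r2, r3)
      bpv("chain", paste(r1, r2, r3))),
    lapply(sort(names(schema$labels)), function(r)
      bpv("relationLabel", paste(r, schema$labels[[r]])))
  )

  nodes <- purrr::pmap(terms, function(id, label, category) {
    n <- list(id = expand_curie(id, prefixes), lbl = label)
    if (category != "none") n$meta <- list(basicPropertyValues = list(bpv("category", category)))
    n
  })

  edge_objs <- purrr::pmap(edges, function(subject, relation, object, provenance,
                                           validation_status, validation_date,
                                           source_relation) {
    pred <- if (relation == SUBCLASS_OF) "is_a" else expand_curie(relation, prefixes)
    e <- list(sub = expand_curie(subject, prefixes), pred = pred,
              obj = expand_curie(object, prefixes))
    bpvs <- list()
    if (provenance != "asserted") bpvs <- c(bpvs, list(bpv("provenance", provenance)))
    if (!is.na(source_relation)) bpvs <- c(bpvs, list(bpv("source_relation", source_relation)))
    if (!is.na(validation_date)) bpvs <- c(bpvs, list(bpv("validation_date", validation_date)))
    if (!is.na(validation_status)) bpvs <- c(bpvs, list(bpv("validation_status", validation_status)))
    if (length(bpvs) > 0L) e$meta <- list(basicPropertyValues = bpvs)
    e
  })

  doc <- list(graphs = list(list(id = onto$id,
                                 meta = list(basicPropertyValues = gmeta),
                                 nodes = nodes, edges = edge_objs)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, null = "null")
  json <- paste0(as.character(json), "\n")
  if (!is.null(path)) {
    writeLines(json, path, sep = "")
    return(invisible(json))
  }
  json
}

bpv <- function(pred, val) list(pred = pred, val = val)

#' Read / write an edge TSV
#'
#' Three or four tab-separated columns `subject`, `relation`, `object`
#' (optionally `provenance`), with a header line. Used to export a saturated
#' closure or import asserted edges.
#'
#' @param path File path (or, for `read_edge_tsv`, literal TSV text).
#' @param edges An edge tibble (e.g. `tidy(saturate(onto))`).
#' @return `read_edge_tsv` returns an edge tibble; `write_edge_tsv` its input,
#'   invisibly.
#' @export
read_edge_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("subject", "relation", "object")
  if (!all(need %in% names(df))) {
    rlang::abort("edge TSV must have header columns subject, relation, object")
  }
  complete_edge_tbl(df)
}

#' @rdname read_edge_tsv
#' @export
write_edge_tsv <- function(edges, path) {
  edges <- sort_edges(complete_edge_tbl(edges))
  readr::write_tsv(edges[c("subject", "relation", "object", "provenance")], path)
  invisible(edges)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
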