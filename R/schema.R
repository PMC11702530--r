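#' Common Relations Ontology identifiers
#'
#' Convenience constants for the object properties used throughout anatomy
#' and cell-type validation: parthood, its bounding-layer specialisation,
#' overlap, connectivity and developmental relations.
#'
#' @format Length-one character constants holding CURIEs.
#' @name relation-constants
NULL

#' @rdname relation-constants
#' @export
PART_OF <- "BFO:0000050"
#' @rdname relation-constants
#' @export
HAS_PART <- "BFO:0000051"
#' @rdname relation-constants
#' @export
OVERLAPS <- "RO:0002131"
#' @rdname relation-constants
#' @export
CONNECTED_TO <- "RO:0002170"
#' @rdname relation-constants
#' @export
DEVELOPS_FROM <- "RO:0002202"
#' @rdname relation-constants
#' @export
HAS_DEV_CONTRIBUTION_FROM <- "RO:0002254"
#' @rdname relation-constants
#' @export
BOUNDING_LAYER_OF <- "RO:0002007"

ccf_predicates <- function() {
  c("ccf_part_of", "ccf_branching_part_of", "ccf_located_in",
    "ccf_is_a", "ccf_characterizes")
}

#' Declare the object properties an ontology may use
#'
#' A property schema names the relations in play and the axioms the reasoner
#' exploits: which relations are transitive, the subproperty hierarchy
#' (e.g. `bounding_layer_of` is a subproperty of `part_of`), and property
#' chains (`r1` composed with `r2` implies `r3`). The reserved token
#' [SUBCLASS_OF] is always declared and may not appear in a chain.
#'
#' @param relations Character vector of relation CURIEs (the token
#'   `subClassOf` is added automatically).
#' @param transitive Character vector, subset of `relations`, relations whose
#'   composition with themselves is entailed.
#' @param sub_property_of Tibble/data frame with columns `child`, `parent`
#'   (both relation CURIEs); must be acyclic.
#' @param chains Tibble/data frame with columns `r1`, `r2`, `r3`: holding
#'   `a r1 b` and `b r2 c` entails `a r3 c`.
#' @param labels Optional named character vector mapping relation CURIEs to
#'   human-readable labels (used in DOT output).
#' @return A `property_schema` object.
#' @examples
#' property_schema(
#'   relations = c(PART_OF, BOUNDING_LAYER_OF),
#'   transitive = PART_OF,
#'   sub_property_of = tibble::tibble(child = BOUNDING_LAYER_OF, parent = PART_OF)
#' )
#' @export
property_schema <- function(relations = character(),
                            transitive = character(),
                            sub_property_of = NULL,
                            chains = NULL,
                            labels = character()) {
  relations <- sort(unique(c(SUBCLASS_OF, relations)))
  sub_property_of <- as_schema_tbl(sub_property_of, c("child", "parent"))
  chains <- as_schema_tbl(chains, c("r1", "r2", "r3"))

  used <- unique(c(transitive, sub_property_of$child, sub_property_of$parent,
                   chains$r1, chains$r2, chains$r3))
  missing <- setdiff(used, relations)
  if (length(missing) > 0L) {
    rlang::abort(paste0("schema refers to undeclared relations: ",
                        paste(missing, collapse = ", ")))
  }
  if (SUBCLASS_OF %in% c(chains$r1, chains$r2, chains$r3)) {
    rlang::abort("subClassOf may not appear as a property-chain component")
  }
  if (SUBCLASS_OF %in% transitive) {
    rlang::abort("subClassOf transitivity is built in; do not declare it")
  }
  check_acyclic_pairs(sub_property_of$child, sub_property_of$parent,
                      what = "sub_property_of")

  schema <- structure(
    list(relations = relations,
         transitive = sort(unique(transitive)),
         sub_property_of = dplyr::arrange(dplyr::distinct(sub_property_of),
                                          .data$child, .data$parent),
         chains = dplyr::arrange(dplyr::distinct(chains),
                                 .data$r1, .data$r2, .data$r3),
         labels = labels),
    class = "property_schema")
  schema
}

as_schema_tbl <- function(x, cols) {
  if (is.null(x)) {
    x <- stats::setNames(rep(list(character()), length(cols)), cols)
    return(tibble::as_tibble(x))
  }
  x <- tibble::as_tibble(x)
  if (!all(cols %in% names(x))) {
    rlang::abort(paste0("expected columns: ", paste(cols, collapse = ", ")))
  }
  x[cols]
}

# Kahn-style cycle check on a pair list; aborts listing cycle members.
check_acyclic_pairs <- function(from, to, what = "graph") {
  nodes <- unique(c(from, to))
  edges <- tibble::tibble(from = from, to = to)
  repeat {
    if (length(nodes) == 0L || nrow(edges) == 0L) return(invisible(TRUE))
    sinks <- setdiff(nodes, edges$from)
    leftover <- setdiff(nodes, c(edges$from, edges$to))
    drop <- union(sinks, leftover)
    if (length(drop) == 0L) {
      rlang::abort(paste0("cycle in ", what, " involving: ",
                          paste(sort(nodes), collapse = ", ")))
    }
    nodes <- setdiff(nodes, drop)
    edges <- edges[!(edges$to %in% drop) & !(edges$from %in% drop), ]
  }
}

#' @export
print.property_schema <- function(x, ...) {
  cat("<property_schema> ", length(x$relations), " relations (",
      length(x$transitive), " transitive, ",
      nrow(x$sub_property_of), " subproperty axioms, ",
      nrow(x$chains), " chains)\n", sep = "")
  invisible(x)
}

#' Reflexive-transitive closure of the subproperty hierarchy
#'
#' Every relation maps at least to itself; declared `sub_property_of` pairs
#' are chased upward, so with `bounding_layer_of` a subproperty of `part_of`,
#' `bounding_layer_of` maps to both relations.
#'
#' @param schema A [property_schema()].
#' @return Named list mapping each declared relation to the character vector
#'   of its superproperties (including itself), sorted.
#' @export
superproperty_closure <- function(schema) {
  stopifnot(inherits(schema, "property_schema"))
  up <- split(schema$sub_property_of$parent, schema$sub_property_of$child)
  out <- lapply(stats::setNames(schema$relations, schema$relations), function(r) {
    seen <- r
    frontier <- r
    while (length(frontier) > 0L) {
      nxt <- setdiff(unique(unlist(up[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    sort(seen)
  })
  out
}

#' Default validation schema
#'
#' Declares the relations exercised by anatomy/cell-type validation:
#' `part_of` (transitive) with `bounding_layer_of` as a subproperty,
#' `has_part`, `overlaps`, `connected_to`, `develops_from` and
#' `has_developmental_contribution_from`. No chains are active by default;
#' callers can declare their own via [property_schema()].
#'
#' @return A [property_schema()].
#' @export
default_schema <- function() {
  property_schema(
    relations = c(PART_OF, HAS_PART, OVERLAPS, CONNECTED_TO, DEVELOPS_FROM,
                  HAS_DEV_CONTRIBUTION_FROM, BOUNDING_LAYER_OF),
    transitive = PART_OF,
    sub_property_of = tibble::tibble(child = BOUNDING_LAYER_OF, parent = PART_OF),
    labels = c(
      stats::setNames("part_of", PART_OF),
      stats::setNames("has_part", HAS_PART),
      stats::setNames("overlaps", OVERLAPS),
      stats::setNames("connected_to", CONNECTED_TO),
      stats::setNames("develops_from", DEVELOPS_FROM),
      stats::setNames("has_developmental_contribution_from", HAS_DEV_CONTRIBUTION_FROM),
      stats::setNames("bounding_layer_of", BOUNDING_LAYER_OF)
    )
  )
}

relation_label <- function(schema, r) {
  lab <- schema$labels[r]
  ifelse(is.na(lab), r, lab)
}
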