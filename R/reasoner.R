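#' Materialize the redundant graph of an ontology
#'
#' Computes the least fixpoint of five inference rules over the asserted
#' logical edges, so every indirect subsumption and existential relationship
#' becomes directly queryable (the "redundant graph" that replaces live
#' triplestore queries):
#'
#' * R1 — `subClassOf` transitivity;
#' * R2 — property hierarchy: an edge under a relation also holds under every
#'   superproperty (e.g. `bounding_layer_of` implies `part_of`);
#' * R3 — declared transitive properties compose with themselves;
#' * R4 — subclass propagation: `a subClassOf b, b r c` entails `a r c`, and
#'   `a r b, b subClassOf c` entails `a r c`, for every object property `r`;
#' * R5 — property chains: `a r1 b, b r2 c` entails `a r3 c` for each declared
#'   chain `(r1, r2) -> r3`.
#'
#' Evaluation is semi-naive (each round joins only against the previous
#' round's new edges plus the accumulated closure) and terminates because the
#' edge space is finite; cyclic inputs are legal. Annotation edges are
#' excluded throughout. Edges in the closure that are not asserted carry
#' provenance `"inferred"`.
#'
#' @param onto An [ontology()].
#' @return A `redundant_graph`: the base ontology plus the saturated closure
#'   (an edge tibble).
#' @examples
#' rg <- saturate(builtin_fixture("kidney"))
#' entails(rg, "CL:0000653", PART_OF, "UBERON:0002113")  # podocyte in kidney
#' @export
saturate <- function(onto) {
  stopifnot(inherits(onto, "ontology"))
  asserted <- onto$edges[onto$edges$provenance == "asserted",
                         c("subject", "relation", "object")]
  asserted <- dplyr::distinct(asserted)
  sup <- superproperty_closure(onto$schema)
  sup_tbl <- purrr::map_dfr(names(sup), function(r) {
    parents <- setdiff(sup[[r]], r)
    if (length(parents) == 0L) return(NULL)
    tibble::tibble(relation = r, parent = parents)
  })
  if (nrow(sup_tbl) == 0L) {
    sup_tbl <- tibble::tibble(relation = character(), parent = character())
  }
  trans <- onto$schema$transitive
  chains <- onto$schema$chains

  closure <- asserted
  delta <- asserted
  while (nrow(delta) > 0L) {
    cand <- dplyr::bind_rows(
      rule_superproperty(delta, sup_tbl),
      rule_transitive(delta, closure, trans),
      rule_subclass_propagation(delta, closure),
      rule_chains(delta, closure, chains)
    )
    if (is.null(cand) || nrow(cand) == 0L) break
    cand <- dplyr::distinct(cand)
    delta <- dplyr::anti_join(cand, closure,
                              by = c("subject", "relation", "object"))
    closure <- dplyr::bind_rows(closure, delta)
  }

  closure <- dplyr::left_join(
    closure,
    dplyr::mutate(asserted, .asserted = TRUE),
    by = c("subject", "relation", "object"))
  closure <- edge_tbl(subject = closure$subject, relation = closure$relation,
                      object = closure$object,
                      provenance = ifelse(is.na(closure$.asserted),
                                          "inferred", "asserted"))
  structure(list(base = onto, closure = sort_edges(closure)),
            class = "redundant_graph")
}

rule_superproperty <- function(delta, sup_tbl) {
  if (nrow(sup_tbl) == 0L) return(NULL)
  out <- dplyr::inner_join(delta, sup_tbl, by = "relation",
                           relationship = "many-to-many")
  if (nrow(out) == 0L) return(NULL)
  tibble::tibble(subject = out$subject, relation = out$parent,
                 object = out$object)
}

# R1 and R3: self-composition of subClassOf and declared transitive relations.
rule_transitive <- function(delta, closure, trans) {
  rels <- c(SUBCLASS_OF, trans)
  d <- delta[delta$relation %in% rels, ]
  if (nrow(d) == 0L) return(NULL)
  c2 <- closure[closure$relation %in% rels, ]
  left <- dplyr::inner_join(d, c2,
                            by = c("object" = "subject", "relation"),
                            suffix = c("", ".y"),
                            relationship = "many-to-many")
  right <- dplyr::inner_join(c2, d,
                             by = c("object" = "subject", "relation"),
                             suffix = c("", ".y"),
                             relationship = "many-to-many")
  out <- dplyr::bind_rows(
    tibble::tibble(subject = left$subject, relation = left$relation,
                   object = left$object.y),
    tibble::tibble(subject = right$subject, relation = right$relation,
                   object = right$object.y))
  out
}

# R4: (a subClassOf b)(b r c) => a r c ; (a r b)(b subClassOf c) => a r c.
rule_subclass_propagation <- function(delta, closure) {
  sc_new <- delta[delta$relation == SUBCLASS_OF, ]
  op_new <- delta[delta$relation != SUBCLASS_OF, ]
  sc_all <- closure[closure$relation == SUBCLASS_OF, ]
  op_all <- closure[closure$relation != SUBCLASS_OF, ]
  join1 <- function(sc, op) {
    if (nrow(sc) == 0L || nrow(op) == 0L) return(NULL)
    j <- dplyr::inner_join(sc, op, by = c("object" = "subject"),
                           suffix = c(".sc", ""),
                           relationship = "many-to-many")
    tibble::tibble(subject = j$subject, relation = j$relation,
                   object = j$object)
  }
  join2 <- function(op, sc) {
    if (nrow(op) == 0L || nrow(sc) == 0L) return(NULL)
    j <- dplyr::inner_join(op, sc, by = c("object" = "subject"),
                           suffix = c("", ".sc"),
                           relationship = "many-to-many")
    tibble::tibble(subject = j$subject, relation = j$relation,
                   object = j$object.sc)
  }
  dplyr::bind_rows(join1(sc_new, op_all), join1(sc_all, op_new),
                   join2(op_new, sc_all), join2(op_all, sc_new))
}

rule_chains <- function(delta, closure, chains) {
  if (nrow(chains) == 0L) return(NULL)
  purrr::pmap_dfr(chains, function(r1, r2, r3) {
    fire <- function(left, right) {
      l <- left[left$relation == r1, ]
      r <- right[right$relation == r2, ]
      if (nrow(l) == 0L || nrow(r) == 0L) return(NULL)
      j <- dplyr::inner_join(l, r, by = c("object" = "subject"),
                             suffix = c("", ".y"),
                             relationship = "many-to-many")
      tibble::tibble(subject = j$subject, relation = r3, object = j$object.y)
    }
    dplyr::bind_rows(fire(delta, closure), fire(closure, delta))
  })
}

#' @export
print.redundant_graph <- function(x, ...) {
  cat("<redundant_graph> ", nrow(x$closure), " edges (",
      sum(x$closure$provenance == "inferred"), " inferred) over ",
      nrow(x$base$terms), " terms\n", sep = "")
  invisible(x)
}

#' Tidy a redundant graph into its closure edge table
#'
#' @param x A `redundant_graph` from [saturate()].
#' @param ... Unused.
#' @return The closure tibble with provenance `asserted`/`inferred`.
#' @method tidy redundant_graph
#' @export
tidy.redundant_graph <- function(x, ...) x$closure

#' One-row summary of a redundant graph
#'
#' @param x A `redundant_graph`.
#' @param ... Unused.
#' @return A one-row tibble of closure counts.
#' @method glance redundant_graph
#' @export
glance.redundant_graph <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x$base$terms),
                 n_closure_edges = nrow(x$closure),
                 n_asserted = sum(x$closure$provenance == "asserted"),
                 n_inferred = sum(x$closure$provenance == "inferred"))
}

#' Does the redundant graph entail a triple?
#'
#' Membership in the saturated closure, with one convention: reflexive
#' subsumption (`a subClassOf a`) is answered `TRUE` for any declared term.
#' No other reflexivity is assumed. Undeclared subjects, objects or relations
#' yield `FALSE` with a warning rather than an error.
#'
#' @param graph A `redundant_graph` from [saturate()].
#' @param subject,object Term CURIEs.
#' @param relation Relation CURIE or [SUBCLASS_OF].
#' @return A single logical.
#' @export
entails <- function(graph, subject, relation, object) {
  stopifnot(inherits(graph, "redundant_graph"))
  terms <- graph$base$terms$id
  if (!subject %in% terms || !object %in% terms ||
      !relation %in% graph$base$schema$relations) {
    rlang::warn("entails() called with undeclared term or relation; returning FALSE",
                class = "ontoview_undeclared")
    return(FALSE)
  }
  if (relation == SUBCLASS_OF && subject == object) return(TRUE)
  cl <- graph$closure
  any(cl$subject == subject & cl$relation == relation & cl$object == object)
}
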