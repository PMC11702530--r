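#' Built-in mini-fixtures
#'
#' Hand-built artifacts small enough to reason about by eye, each anchoring
#' a well-known validation scenario:
#'
#' * `kidney` — ontology with the podocyte classification chain (podocyte is
#'   an epithelial cell is a cell) and the glomerular partonomy (podocyte
#'   part_of glomerular visceral epithelium, ... , nephron part_of kidney),
#'   plus `kidney capsule bounding_layer_of kidney` with `bounding_layer_of`
#'   a subproperty of `part_of` — saturation must recover that the podocyte
#'   is part of the kidney and the capsule is part of the kidney.
#' * `cornea` — ontology where the keratocyte sits in the substantia propria
#'   of the cornea (which spans anterior and posterior stroma), the anterior
#'   stroma is part of the substantia propria, and a telocyte term is
#'   unattached — the scenario where a recorded keratocyte/anterior-stroma
#'   link fails and the most precise enclosing structure in the table is the
#'   cornea. Identifiers not fixed by convention here (anterior stroma,
#'   telocyte) are illustrative.
#' * `endothelium` — ontology around the vasa recta limbs in which the
#'   generic term `endothelium` bears no relation to either limb (the
#'   generic-term-under-a-specific-one error pattern), while each limb's
#'   endothelial cell is asserted part of its limb.
#' * `table1_extract` — the two-row kidney table extract that records
#'   `endothelium` under each vasa recta limb (note one identifier cell is
#'   printed with a stray space, which the parser normalizes).
#' * `fig2_rows` — kidney table rows whose fourth data row links renal
#'   corpuscle to nephron and nephron to kidney.
#' * `cornea_rows` — two table rows placing keratocyte and telocyte in the
#'   anterior stroma of the cornea.
#'
#' @param name Fixture name.
#' @return An [ontology()] for the ontology fixtures, an `asctb_table` for
#'   the table fixtures.
#' @examples
#' rg <- saturate(builtin_fixture("kidney"))
#' entails(rg, "CL:0000653", PART_OF, "UBERON:0002113")
#' @export
builtin_fixture <- function(name = c("kidney", "cornea", "endothelium",
                                     "table1_extract", "fig2_rows",
                                     "cornea_rows")) {
  name <- match.arg(name)
  switch(name,
    kidney = fixture_kidney(),
    cornea = fixture_cornea(),
    endothelium = fixture_endothelium(),
    table1_extract = parse_asctb(fixture_file("table1_extract.csv"),
                                 table_id = "table1_extract"),
    fig2_rows = parse_asctb(fixture_file("fig2_rows.csv"),
                            table_id = "fig2_rows"),
    cornea_rows = fixture_cornea_rows())
}

fixture_file <- function(fname) {
  path <- system.file("extdata", fname, package = "ontoview")
  if (!nzchar(path)) rlang::abort(paste0("fixture file missing: ", fname))
  path
}

fixture_kidney <- function() {
  terms <- dplyr::bind_rows(
    term_tbl("CL:0000653", "podocyte", "CT"),
    term_tbl("CL:0000066", "epithelial cell", "CT"),
    term_tbl("CL:0000000", "cell", "CT"),
    term_tbl("UBERON:0005751", "glomerular visceral epithelium", "AS"),
    term_tbl("UBERON:0000074", "renal glomerulus", "AS"),
    term_tbl("UBERON:0001229", "renal corpuscle", "AS"),
    term_tbl("UBERON:0001285", "nephron", "AS"),
    term_tbl("UBERON:0002113", "kidney", "AS"),
    term_tbl("UBERON:0002015", "kidney capsule", "AS"))
  edges <- dplyr::bind_rows(
    edge_tbl("CL:0000653", SUBCLASS_OF, "CL:0000066"),
    edge_tbl("CL:0000066", SUBCLASS_OF, "CL:0000000"),
    edge_tbl("CL:0000653", PART_OF, "UBERON:0005751"),
    edge_tbl("UBERON:0005751", PART_OF, "UBERON:0000074"),
    edge_tbl("UBERON:0000074", PART_OF, "UBERON:0001229"),
    edge_tbl("UBERON:0001229", PART_OF, "UBERON:0001285"),
    edge_tbl("UBERON:0001285", PART_OF, "UBERON:0002113"),
    edge_tbl("UBERON:0002015", BOUNDING_LAYER_OF, "UBERON:0002113"))
  ontology(terms = terms, edges = edges, id = "kidney_fixture")
}

fixture_cornea <- function() {
  terms <- dplyr::bind_rows(
    term_tbl("CL:0002363", "keratocyte", "CT"),
    term_tbl("CL:4033054", "telocyte", "CT"),
    term_tbl("UBERON:0001777", "substantia propria of cornea", "AS"),
    term_tbl("UBERON:8000001", "anterior stroma of cornea", "AS"),
    term_tbl("UBERON:0000964", "cornea", "AS"))
  edges <- dplyr::bind_rows(
    edge_tbl("CL:0002363", PART_OF, "UBERON:0001777"),
    edge_tbl("UBERON:0001777", PART_OF, "UBERON:0000964"),
    edge_tbl("UBERON:8000001", PART_OF, "UBERON:0001777"))
  ontology(terms = terms, edges = edges, id = "cornea_fixture")
}

fixture_endothelium <- function() {
  terms <- dplyr::bind_rows(
    term_tbl("UBERON:0009202", "vasa recta descending limb", "AS"),
    term_tbl("UBERON:0009091", "vasa recta ascending limb", "AS"),
    term_tbl("UBERON:0001986", "endothelium", "AS"),
    term_tbl("UBERON:0000483", "epithelium", "AS"),
    term_tbl("UBERON:0002113", "kidney", "AS"),
    term_tbl("CL:1001285", "vasa recta descending limb cell", "CT"),
    term_tbl("CL:1001131", "vasa recta ascending limb cell", "CT"))
  edges <- dplyr::bind_rows(
    edge_tbl("UBERON:0009202", PART_OF, "UBERON:0002113"),
    edge_tbl("UBERON:0009091", PART_OF, "UBERON:0002113"),
    edge_tbl("UBERON:0001986", SUBCLASS_OF, "UBERON:0000483"),
    edge_tbl("CL:1001285", PART_OF, "UBERON:0009202"),
    edge_tbl("CL:1001131", PART_OF, "UBERON:0009091"))
  ontology(terms = terms, edges = edges, id = "endothelium_fixture")
}

fixture_cornea_rows <- function() {
  csv <- paste(
    "AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID,CT/1/LABEL,CT/1/ID",
    "cornea,UBERON:0000964,anterior stroma of cornea,UBERON:8000001,keratocyte,CL:0002363",
    "cornea,UBERON:0000964,anterior stroma of cornea,UBERON:8000001,telocyte,CL:4033054",
    sep = "\n")
  parse_asctb(csv, table_id = "cornea_rows")
}

#' Parameters for the random-ontology generator
#'
#' @param n_terms_per_category Named integer vector over `AS` and `CT`.
#' @param subclass_density Probability that any ordered higher-to-lower-index
#'   pair within a category gets a `subClassOf` edge.
#' @param partonomy_density Same, for `part_of`.
#' @param extra_relations Named numeric vector mapping additional relation
#'   CURIEs to their attachment probability (defaults exercise the
#'   subproperty rule via `bounding_layer_of` and a non-grouping relation,
#'   `overlaps`).
#' @param seed Integer seed; identical parameters and seed give identical
#'   ontologies.
#' @return A `fixture_params` object.
#' @export
fixture_params <- function(n_terms_per_category = c(AS = 30L, CT = 20L),
                           subclass_density = 0.05,
                           partonomy_density = 0.05,
                           extra_relations = stats::setNames(
                             c(0.02, 0.02), c(BOUNDING_LAYER_OF, OVERLAPS)),
                           seed = 1L) {
  probs <- c(subclass_density, partonomy_density, unname(extra_relations))
  if (any(probs < 0 | probs > 1)) rlang::abort("probabilities must lie in [0, 1]")
  if (any(n_terms_per_category < 1L)) rlang::abort("need at least one term per category")
  structure(list(n_terms_per_category = n_terms_per_category,
                 subclass_density = subclass_density,
                 partonomy_density = partonomy_density,
                 extra_relations = extra_relations,
                 seed = as.integer(seed)),
            class = "fixture_params")
}

#' Generate a seeded random ontology
#'
#' Terms are indexed within each category and edges only ever point from a
#' higher-index subject to a lower-index object, so the `subClassOf` and
#' `part_of` graphs are acyclic by construction (no cycle detection needed).
#' Extra relations are sprinkled over the full index order with their
#' attachment probabilities. The generator restores the caller's random
#' state, and identical parameters plus seed reproduce the same ontology.
#'
#' @param params A [fixture_params()].
#' @return An [ontology()] using [default_schema()].
#' @export
random_ontology <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(params$seed)

  make_ids <- function(cat, n) sprintf("EX:%s%03d", cat, seq_len(n))
  ids <- list(AS = make_ids("AS", params$n_terms_per_category[["AS"]]),
              CT = make_ids("CT", params$n_terms_per_category[["CT"]]))
  terms <- dplyr::bind_rows(
    term_tbl(ids$AS, paste("random structure", seq_along(ids$AS)), "AS"),
    term_tbl(ids$CT, paste("random cell type", seq_along(ids$CT)), "CT"))

  pairs_within <- function(v) {
    if (length(v) < 2L) {
      return(tibble::tibble(subject = character(), object = character()))
    }
    idx <- which(upper.tri(matrix(NA, length(v), length(v))), arr.ind = TRUE)
    # subject has the higher index: edges point toward lower-index terms
    tibble::tibble(subject = v[idx[, "col"]], object = v[idx[, "row"]])
  }
  sample_edges <- function(pairs, relation, p) {
    if (p <= 0 || nrow(pairs) == 0L) return(NULL)
    hit <- stats::runif(nrow(pairs)) < p
    if (!any(hit)) return(NULL)
    edge_tbl(pairs$subject[hit], relation, pairs$object[hit])
  }

  all_ids <- c(ids$AS, ids$CT)
  edges <- dplyr::bind_rows(
    sample_edges(pairs_within(ids$AS), SUBCLASS_OF, params$subclass_density),
    sample_edges(pairs_within(ids$CT), SUBCLASS_OF, params$subclass_density),
    sample_edges(pairs_within(ids$AS), PART_OF, params$partonomy_density),
    sample_edges(pairs_within(ids$CT), PART_OF, params$partonomy_density),
    purrr::imap_dfr(as.list(params$extra_relations), function(p, rel) {
      out <- sample_edges(pairs_within(all_ids), rel, p)
      out %||% edge_tbl()
    }))
  ontology(terms = terms, edges = edges,
           id = paste0("random_", params$seed))
}
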