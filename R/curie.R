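#' Prefix maps and CURIE handling
#'
#' A prefix map associates short namespace tokens (`UBERON`, `CL`, `BFO`, ...)
#' with IRI stems, so compact identifiers (CURIEs) of the form
#' `prefix:local_id` can be expanded to full IRIs and contracted back.
#' Expansion followed by contraction is the identity on declared prefixes.
#'
#' @param ... Named character arguments, one IRI stem per prefix token, or a
#'   single named character vector.
#' @return A `prefix_map` object (a named character vector).
#' @examples
#' pm <- prefix_map(UBERON = "http://purl.obolibrary.org/obo/UBERON_")
#' expand_curie("UBERON:0002113", pm)
#' @export
prefix_map <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.character(dots[[1]])) {
    entries <- dots[[1]]
  } else {
    entries <- unlist(dots)
  }
  entries <- entries[order(names(entries))]
  if (anyDuplicated(names(entries)) > 0L) {
    rlang::abort("prefix map has duplicated prefixes")
  }
  if (any(!nzchar(names(entries)))) {
    rlang::abort("every prefix token must be non-empty")
  }
  if (anyDuplicated(unname(entries)) > 0L) {
    rlang::abort("prefix map must be injective: two prefixes share an IRI stem")
  }
  structure(entries, class = "prefix_map")
}

#' Default OBO-style prefix map
#'
#' Covers the namespaces seen in anatomy/cell-type validation work:
#' Uberon, the Cell Ontology (and its provisional extension PCL), the
#' Foundational Model of Anatomy, BFO and the Relations Ontology, plus the
#' bespoke `ccf` namespace used for table-derived annotation predicates.
#'
#' @return A [prefix_map()].
#' @export
default_prefixes <- function() {
  prefix_map(
    UBERON = "http://purl.obolibrary.org/obo/UBERON_",
    CL     = "http://purl.obolibrary.org/obo/CL_",
    PCL    = "http://purl.obolibrary.org/obo/PCL_",
    FMA    = "http://purl.obolibrary.org/obo/FMA_",
    BFO    = "http://purl.obolibrary.org/obo/BFO_",
    RO     = "http://purl.obolibrary.org/obo/RO_",
    EX     = "http://example.org/EX_",
    ccf    = "http://purl.org/ccf/ccf_"
  )
}

#' @export
print.prefix_map <- function(x, ...) {
  cat("<prefix_map> ", length(x), " prefixes\n", sep = "")
  for (p in names(x)) cat("  ", p, " -> ", x[[p]], "\n", sep = "")
  invisible(x)
}

#' Test whether strings are well-formed CURIEs
#'
#' A CURIE is `prefix:local_id` with a non-empty prefix and local id. The
#' reserved token `subClassOf` is not a CURIE.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_curie <- function(x) {
  stringr::str_detect(x, "^[A-Za-z_][A-Za-z0-9_.-]*:\\S+$") & x != SUBCLASS_OF
}

#' Normalize a raw identifier cell into a CURIE
#'
#' Strips surrounding and internal whitespace (printed tables occasionally
#' contain identifiers such as `"CL: 1001131"`). Returns `NA` for cells that
#' do not normalize to a well-formed CURIE.
#'
#' @param x Character vector of raw identifier strings.
#' @return Character vector of CURIEs or `NA`.
#' @export
normalize_curie <- function(x) {
  out <- stringr::str_replace_all(stringr::str_trim(x), "\\s+", "")
  ifelse(!is.na(out) & is_curie(out), out, NA_character_)
}

#' Expand CURIEs to IRIs / contract IRIs to CURIEs
#'
#' The reserved relation token `subClassOf` passes through unchanged in both
#' directions. Contraction matches the longest declared stem; IRIs under no
#' declared stem pass through unchanged (so foreign identifiers survive a
#' round-trip).
#'
#' @param x Character vector of CURIEs (for `expand_curie`) or IRIs (for
#'   `contract_iri`).
#' @param prefixes A [prefix_map()].
#' @return Character vector.
#' @export
expand_curie <- function(x, prefixes) {
  vapply(x, function(id) {
    if (is.na(id) || id == SUBCLASS_OF) return(id)
    m <- stringr::str_match(id, "^([A-Za-z_][A-Za-z0-9_.-]*):(\\S+)$")
    if (is.na(m[1, 1]) || !(m[1, 2] %in% names(prefixes))) return(id)
    paste0(prefixes[[m[1, 2]]], m[1, 3])
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname expand_curie
#' @export
contract_iri <- function(x, prefixes) {
  stems <- unname(unlist(prefixes))
  toks <- names(prefixes)
  ord <- order(nchar(stems), decreasing = TRUE)
  stems <- stems[ord]
  toks <- toks[ord]
  vapply(x, function(iri) {
    if (is.na(iri) || iri == SUBCLASS_OF) return(iri)
    for (i in seq_along(stems)) {
      if (startsWith(iri, stems[[i]])) {
        return(paste0(toks[[i]], ":", substring(iri, nchar(stems[[i]]) + 1L)))
      }
    }
    iri
  }, character(1), USE.NAMES = FALSE)
}

#' The reserved subsumption relation token
#'
#' `subClassOf` is modeled as a reserved token distinct from every object
#' property, so it can never collide with a CURIE.
#'
#' @format A length-one character constant.
#' @export
SUBCLASS_OF <- "subClassOf"
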