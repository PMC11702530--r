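#' Styling for DOT output
#'
#' Nodes are colored by term category (anatomical structures red, cell types
#' blue, matching the usual table-graph rendering) and edges by validation
#' status (unsupported relationships red, suggested replacements green).
#'
#' @param node_color_by_category Named character vector over
#'   `AS`, `CT`, `B`, `none`.
#' @param edge_color_by_status Named character vector over `valid`,
#'   `valid_reversed`, `suggested`, `invalid`, `unresolved_term`, `skipped`.
#' @param rankdir Graphviz layout direction (`"LR"`, `"TB"`, ...).
#' @return A `dot_style` object.
#' @export
dot_style <- function(node_color_by_category = c(AS = "red", CT = "blue",
                                                 B = "orange", none = "black"),
                      edge_color_by_status = c(valid = "black",
                                               valid_reversed = "gray40",
                                               suggested = "green",
                                               invalid = "red",
                                               unresolved_term = "purple",
                                               skipped = "gray80"),
                      rankdir = "RL") {
  need <- c("valid", "valid_reversed", "suggested", "invalid")
  if (!all(need %in% names(edge_color_by_status))) {
    rlang::abort("edge_color_by_status must map every validation status")
  }
  structure(list(node_color_by_category = node_color_by_category,
                 edge_color_by_status = edge_color_by_status,
                 rankdir = rankdir),
            class = "dot_style")
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

color_or <- function(map, key, default = "black") {
  v <- unname(map[key])
  ifelse(is.na(v) | is.na(key), default, v)
}

#' Emit a Graphviz DOT rendering
#'
#' For a validation report: one node per term, one edge per outcome colored
#' by status. A suggested outcome contributes two edges — the original
#' (unsupported) relationship in the invalid color and the suggested
#' replacement in the suggested color, labeled with the suggested relation.
#' For a view: logical edges labeled with their relation, annotation edges
#' dashed. Output ordering is sorted by CURIE, so equal inputs give
#' byte-identical text.
#'
#' @param x A `validation_report` or `view_ontology`.
#' @param style A [dot_style()].
#' @return DOT text.
#' @export
emit_dot <- function(x, style = dot_style()) UseMethod("emit_dot")

#' @export
emit_dot.validation_report <- function(x, style = dot_style()) {
  oc <- x$outcomes
  cat_of <- function(pair, side) {
    if (length(pair) == 0L) return(character())
    stringr::str_split_fixed(pair, "_", 2)[, side]
  }
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = oc$subject, label = oc$subject_label,
                   category = cat_of(oc$category_pair, 1L)),
    tibble::tibble(id = oc$object, label = oc$object_label,
                   category = cat_of(oc$category_pair, 2L)),
    tibble::tibble(id = oc$suggested_object[!is.na(oc$suggested_object)],
                   label = "", category = "AS")) |>
    dplyr::distinct(.data$id, .keep_all = TRUE) |>
    dplyr::arrange(.data$id)

  node_lines <- purrr::pmap_chr(nodes, function(id, label, category) {
    col <- color_or(style$node_color_by_category, category)
    paste0("  ", dot_quote(id), " [label=", dot_quote(if (nzchar(label)) label else id),
           ", color=", col, "];")
  })

  edge_rows <- purrr::pmap_dfr(oc, function(subject, object, predicate, status,
                                            suggested_relation, suggested_object,
                                            ...) {
    base_col <- if (status == "suggested") {
      color_or(style$edge_color_by_status, "invalid")
    } else {
      color_or(style$edge_color_by_status, status)
    }
    out <- tibble::tibble(from = subject, to = object, label = predicate,
                          color = base_col, styl = "solid")
    if (status == "suggested") {
      out <- dplyr::bind_rows(out, tibble::tibble(
        from = subject, to = suggested_object,
        label = suggested_relation,
        color = style$edge_color_by_status[["suggested"]], styl = "solid"))
    }
    out
  })
  edge_lines <- format_dot_edges(edge_rows)
  dot_document(paste0("validation_", x$table_id), style, node_lines, edge_lines)
}

#' @export
emit_dot.view_ontology <- function(x, style = dot_style()) {
  nodes <- dplyr::arrange(x$terms, .data$id)
  node_lines <- purrr::pmap_chr(nodes, function(id, label, category) {
    col <- color_or(style$node_color_by_category, category)
    paste0("  ", dot_quote(id), " [label=", dot_quote(if (nzchar(label)) label else id),
           ", color=", col, "];")
  })
  lg <- x$logical_edges
  an <- x$annotation_edges
  edge_rows <- dplyr::bind_rows(
    tibble::tibble(from = lg$subject, to = lg$object,
                   label = unname(relation_label(x$schema, lg$relation)),
                   color = ifelse(!is.na(lg$validation_status) &
                                    lg$validation_status == "suggested",
                                  style$edge_color_by_status[["suggested"]],
                                  "black"),
                   styl = "solid"),
    tibble::tibble(from = an$subject, to = an$object,
                   label = an$relation, color = "gray60", styl = "dashed"))
  edge_lines <- format_dot_edges(edge_rows)
  dot_document(x$id, style, node_lines, edge_lines)
}

format_dot_edges <- function(edge_rows) {
  if (is.null(edge_rows) || nrow(edge_rows) == 0L) return(character())
  edge_rows <- dplyr::arrange(edge_rows, .data$from, .data$to, .data$label,
                              .data$color)
  purrr::pmap_chr(edge_rows, function(from, to, label, color, styl) {
    paste0("  ", dot_quote(from), " -> ", dot_quote(to),
           " [label=", dot_quote(label), ", color=", color,
           ", style=", styl, "];")
  })
}

dot_document <- function(name, style, node_lines, edge_lines) {
  paste0(c(paste0("digraph ", dot_quote(name), " {"),
           paste0("  rankdir=", style$rankdir, ";"),
           node_lines, edge_lines, "}", ""),
         collapse = "\n")
}

#' Emit a validation report as CSV
#'
#' One row per outcome with subject/object identifiers and labels, the table
#' predicate, the status, the matched or suggested relation and target, and
#' the source rows; followed by a blank line and a `status,count` summary
#' block.
#'
#' @param report A `validation_report`.
#' @return CSV text.
#' @export
emit_validation_csv <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  oc <- report$outcomes
  rows <- tibble::tibble(
    subject_id = oc$subject, subject_label = oc$subject_label,
    predicate = oc$predicate, object_id = oc$object,
    object_label = oc$object_label, status = oc$status,
    matched_relation = oc$matched_relation %|% "",
    suggested_relation = oc$suggested_relation %|% "",
    suggested_object = oc$suggested_object %|% "",
    source_rows = purrr::map_chr(oc$sources, function(s) {
      if (is.null(s) || nrow(s) == 0L) return("")
      paste(sort(unique(s$row)), collapse = ";")
    }))
  counts <- tibble::tibble(status = names(report$counts),
                           count = unname(report$counts))
  paste0(readr::format_csv(rows), "\n", readr::format_csv(counts))
}

#' Plot validation status counts
#'
#' A bar chart of outcome statuses, colored with the same palette as the DOT
#' reports.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tibble::tibble(status = names(object$counts),
                       count = unname(object$counts))
  df <- df[df$count > 0L, ]
  pal <- dot_style()$edge_color_by_status
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$count,
                                   fill = .data$status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = NULL, y = "triples",
                  title = paste0("Validation of ", object$table_id)) +
    ggplot2::theme_minimal()
}

#' Plot a view as a node-link diagram
#'
#' Uses a simple layered layout (depth below the view's roots along the
#' grouping relations) — adequate for the small views this package builds;
#' render the DOT output with Graphviz for publication figures.
#'
#' @param object A `view_ontology`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot view_ontology
#' @export
autoplot.view_ontology <- function(object, ...) {
  ed <- object$logical_edges
  terms <- object$terms
  depth <- stats::setNames(rep(0L, nrow(terms)), terms$id)
  changed <- TRUE
  guard <- 0L
  while (changed && guard < nrow(terms) + 1L) {
    changed <- FALSE
    guard <- guard + 1L
    for (i in seq_len(nrow(ed))) {
      d <- depth[[ed$object[i]]] + 1L
      if (depth[[ed$subject[i]]] < d) {
        depth[[ed$subject[i]]] <- d
        changed <- TRUE
      }
    }
  }
  terms$depth <- unname(depth[terms$id])
  terms <- terms |>
    dplyr::group_by(.data$depth) |>
    dplyr::mutate(xpos = dplyr::row_number() - (dplyr::n() + 1) / 2) |>
    dplyr::ungroup()
  pos <- stats::setNames(seq_len(nrow(terms)), terms$id)
  seg <- tibble::tibble(x = terms$xpos[pos[ed$subject]],
                        y = -terms$depth[pos[ed$subject]],
                        xend = terms$xpos[pos[ed$object]],
                        yend = -terms$depth[pos[ed$object]],
                        relation = unname(relation_label(object$schema, ed$relation)))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$relation),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          color = "gray50") +
    ggplot2::geom_label(data = terms,
                        ggplot2::aes(x = .data$xpos, y = -.data$depth,
                                     label = ifelse(nzchar(.data$label),
                                                    .data$label, .data$id),
                                     fill = .data$category),
                        size = 3) +
    ggplot2::scale_fill_manual(values = c(AS = "#f8b4b4", CT = "#b4d0f8",
                                          B = "#f8e0b4", none = "white")) +
    ggplot2::labs(title = object$id, x = NULL, y = NULL, fill = "category") +
    ggplot2::theme_void()
}
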