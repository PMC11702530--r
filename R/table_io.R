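#' Parse an ASCT+B-style CSV table
#'
#' ASCT+B tables carry anatomical structures (AS), cell types (CT) and
#' biomarkers (B) in columns named `CATEGORY/index/FIELD` (e.g. `AS/4/LABEL`,
#' `AS/4/ID`). Rows encode hierarchy by adjacency: each term is more specific
#' than the term to its left. Leading metadata rows before the header line
#' are skipped; cell whitespace is trimmed. Identifier cells that do not
#' normalize to a CURIE are kept verbatim and later reported as unresolved
#' terms rather than raising an error.
#'
#' @param source Path to a CSV file, or literal CSV text.
#' @param prefixes A [prefix_map()] (carried through to the hierarchy).
#' @param table_id Identifier recorded on the parsed table.
#' @return An `asctb_table`: header descriptors plus a row tibble.
#' @export
parse_asctb <- function(source, prefixes = default_prefixes(),
                        table_id = "asctb_table") {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n"))
  }
  header_pat <- "^(AS|CT|B)/[0-9]+/[A-Z]+$"
  is_header <- vapply(lines, function(l) {
    cells <- stringr::str_trim(scan_csv_line(l))
    any(grepl(header_pat, cells))
  }, logical(1), USE.NAMES = FALSE)
  hdr_idx <- which(is_header)[1]
  if (is.na(hdr_idx)) {
    rlang::abort("no recognizable CATEGORY/index/FIELD header row found")
  }
  body <- paste(lines[hdr_idx:length(lines)], collapse = "\n")
  df <- readr::read_csv(I(body), col_types = readr::cols(.default = readr::col_character()),
                        na = character(), trim_ws = TRUE,
                        name_repair = "minimal", progress = FALSE)
  df <- tibble::as_tibble(df, .name_repair = "minimal")

  hd <- stringr::str_match(names(df), "^(AS|CT|B|REF)/([0-9]+)(?:/([A-Z]+))?$")
  headers <- tibble::tibble(column = names(df),
                            category = hd[, 2],
                            index = suppressWarnings(as.integer(hd[, 3])),
                            field = hd[, 4])
  keep <- !is.na(headers$category) & headers$category != "REF"
  headers <- headers[keep, ]
  headers$field[is.na(headers$field)] <- "LABEL"
  df <- df[headers$column]
  ok <- headers |>
    dplyr::filter(.data$field == "ID") |>
    dplyr::distinct(.data$category, .data$index)
  if (nrow(ok) == 0L && nrow(df) > 0L) {
    rlang::abort("header declares no CATEGORY/index/ID columns")
  }
  structure(list(headers = headers, rows = df, prefixes = prefixes,
                 table_id = table_id),
            class = "asctb_table")
}

scan_csv_line <- function(l) {
  out <- tryCatch(
    utils::read.csv(text = l, header = FALSE, colClasses = "character"),
    error = function(e) NULL)
  if (is.null(out) || nrow(out) == 0L) return("")
  as.character(out[1, ])
}

#' @export
print.asctb_table <- function(x, ...) {
  cat("<asctb_table> ", x$table_id, ": ", nrow(x$rows), " rows, ",
      nrow(x$headers), " typed columns\n", sep = "")
  invisible(x)
}

#' Extract hierarchy triples from a parsed ASCT+B table
#'
#' Within each row, adjacent filled columns form object (left) / subject
#' (right) pairs. Blank cells are skipped so the most specific filled entry
#' links onward. Per standard operating procedure the predicate depends on
#' the category pair:
#'
#' * AS to AS — `ccf_part_of` (organ tables) or `ccf_branching_part_of`
#'   (vasculature tables, `table_kind = "vasculature"`);
#' * first filled CT to the last filled AS — `ccf_located_in`;
#' * adjacent CT columns — `ccf_is_a` (more specific type on the right);
#' * each B to the last filled CT — `ccf_characterizes`.
#'
#' Duplicate (subject, predicate, object) triples are merged with all source
#' coordinates retained. Adjacent cells carrying the same identifier produce
#' a triple flagged `self_reference` instead of being dropped silently.
#'
#' @param table An `asctb_table` from [parse_asctb()].
#' @param table_kind `"organ"` or `"vasculature"`.
#' @return A `term_hierarchy`: a triple tibble, a term tibble with category
#'   tags and a `resolved` flag, and the table id.
#' @export
extract_triples <- function(table, table_kind = c("organ", "vasculature")) {
  stopifnot(inherits(table, "asctb_table"))
  table_kind <- match.arg(table_kind)
  as_as_pred <- if (table_kind == "organ") "ccf_part_of" else "ccf_branching_part_of"

  cells_for <- function(row_i, category) {
    idx <- sort(unique(table$headers$index[table$headers$category == category]))
    out <- purrr::map_dfr(idx, function(i) {
      col_of <- function(field) {
        col <- table$headers$column[table$headers$category == category &
                                    table$headers$index == i &
                                    table$headers$field == field]
        if (length(col) == 0L) return(NA_character_)
        val <- stringr::str_trim(table$rows[[col[[1]]]][row_i])
        if (is.na(val) || !nzchar(val)) NA_character_ else val
      }
      raw_id <- col_of("ID")
      tibble::tibble(category = category, index = i,
                     label = col_of("LABEL") %|% "",
                     raw_id = raw_id,
                     id = normalize_curie(raw_id) %|% raw_id,
                     column = paste0(category, "/", i))
    })
    if (nrow(out) == 0L || !"raw_id" %in% names(out)) {
      return(tibble::tibble(category = character(), index = integer(),
                            label = character(), raw_id = character(),
                            id = character(), column = character()))
    }
    out[!is.na(out$raw_id), ]
  }

  triples <- list()
  terms <- list()
  add_triple <- function(sub, pred, obj, pair, row_i) {
    triples[[length(triples) + 1L]] <<- tibble::tibble(
      subject = sub$id, subject_label = sub$label,
      predicate = pred, object = obj$id, object_label = obj$label,
      category_pair = pair,
      self_reference = identical(sub$id, obj$id),
      row = row_i, subject_col = sub$column, object_col = obj$column)
  }

  for (row_i in seq_len(nrow(table$rows))) {
    as_cells <- cells_for(row_i, "AS")
    ct_cells <- cells_for(row_i, "CT")
    b_cells <- cells_for(row_i, "B")
    terms[[length(terms) + 1L]] <- dplyr::bind_rows(as_cells, ct_cells, b_cells)
    if (nrow(as_cells) + nrow(ct_cells) + nrow(b_cells) == 0L) {
      rlang::warn(paste0("row ", row_i, " has no identifier cells; skipped"))
      next
    }
    if (nrow(as_cells) >= 2L) {
      for (k in 2:nrow(as_cells)) {
        add_triple(as_cells[k, ], as_as_pred, as_cells[k - 1L, ], "AS_AS", row_i)
      }
    }
    if (nrow(ct_cells) >= 1L && nrow(as_cells) >= 1L) {
      add_triple(ct_cells[1L, ], "ccf_located_in",
                 as_cells[nrow(as_cells), ], "CT_AS", row_i)
    }
    if (nrow(ct_cells) >= 2L) {
      for (k in 2:nrow(ct_cells)) {
        add_triple(ct_cells[k, ], "ccf_is_a", ct_cells[k - 1L, ], "CT_CT", row_i)
      }
    }
    if (nrow(b_cells) >= 1L && nrow(ct_cells) >= 1L) {
      for (k in seq_len(nrow(b_cells))) {
        add_triple(b_cells[k, ], "ccf_characterizes",
                   ct_cells[nrow(ct_cells), ], "B_CT", row_i)
      }
    }
  }

  triples <- dplyr::bind_rows(triples)
  if (nrow(triples) == 0L) {
    triples <- tibble::tibble(subject = character(), subject_label = character(),
                              predicate = character(), object = character(),
                              object_label = character(),
                              category_pair = character(),
                              self_reference = logical(), row = integer(),
                              subject_col = character(), object_col = character())
  }
  triples <- triples |>
    dplyr::group_by(.data$subject, .data$predicate, .data$object) |>
    dplyr::summarise(
      subject_label = dplyr::first(.data$subject_label),
      object_label = dplyr::first(.data$object_label),
      category_pair = dplyr::first(.data$category_pair),
      self_reference = any(.data$self_reference),
      sources = list(dplyr::pick("row", "subject_col", "object_col")),
      first_row = min(c(.data$row, Inf)), .groups = "drop") |>
    dplyr::arrange(.data$first_row, .data$subject, .data$predicate, .data$object) |>
    dplyr::select("subject", "subject_label", "predicate", "object",
                  "object_label", "category_pair", "self_reference", "sources")

  terms <- dplyr::bind_rows(terms)
  if (nrow(terms) == 0L) {
    terms <- tibble::tibble(id = character(), label = character(),
                            category = character(), resolved = logical())
  } else {
    terms <- terms |>
      dplyr::transmute(id = .data$id, label = .data$label,
                       category = .data$category,
                       resolved = is_curie(.data$id)) |>
      dplyr::distinct(.data$id, .keep_all = TRUE) |>
      dplyr::arrange(.data$id)
  }

  structure(list(triples = triples, terms = terms, table_id = table$table_id,
                 prefixes = table$prefixes),
            class = "term_hierarchy")
}

`%|%` <- function(x, y) ifelse(is.na(x), y, x)

#' @export
print.term_hierarchy <- function(x, ...) {
  cat("<term_hierarchy> ", x$table_id, ": ", nrow(x$triples), " triples over ",
      nrow(x$terms), " terms\n", sep = "")
  invisible(x)
}

#' Tidy a term hierarchy into its triple table
#'
#' @param x A `term_hierarchy` from [extract_triples()].
#' @param ... Unused.
#' @return The triple tibble.
#' @method tidy term_hierarchy
#' @export
tidy.term_hierarchy <- function(x, ...) x$triples

#' Flatten an ontology view back into an ASCT+B-style table
#'
#' Emits one row per maximal root-to-leaf path over the view's logical edges
#' restricted to `relations` (edges point from the more specific subject to
#' its parent object, so children of `x` are subjects of edges into `x`).
#' Terms with multiple parents appear on multiple rows. Columns follow the
#' `CATEGORY/index/LABEL` + `CATEGORY/index/ID` convention, with the index
#' counting positions of that category along the path.
#'
#' @param view A `view_ontology` (see [extract_subset()]).
#' @param root CURIE of the path root (leftmost column).
#' @param relations Relations whose edges define the paths.
#' @return CSV text.
#' @export
emit_table <- function(view, root, relations = c(SUBCLASS_OF, PART_OF)) {
  stopifnot(inherits(view, "view_ontology"))
  edges <- view$logical_edges[view$logical_edges$relation %in% relations, ]
  if (!root %in% view$terms$id) rlang::abort(paste0("root not in view: ", root))
  check_acyclic_pairs(edges$object, edges$subject, what = "view paths")
  children <- split(edges$subject, edges$object)

  paths <- list()
  walk <- function(path) {
    kids <- sort(unique(children[[path[length(path)]]]))
    kids <- setdiff(kids, path)
    if (length(kids) == 0L) {
      paths[[length(paths) + 1L]] <<- path
    } else {
      for (k in kids) walk(c(path, k))
    }
  }
  walk(root)

  labels <- stats::setNames(view$terms$label, view$terms$id)
  cats <- stats::setNames(view$terms$category, view$terms$id)
  rows <- purrr::map(paths, function(p) {
    counts <- c(AS = 0L, CT = 0L, B = 0L)
    cells <- list()
    for (t in p) {
      cat_t <- cats[[t]]
      if (is.na(cat_t) || cat_t == "none") cat_t <- "AS"
      counts[[cat_t]] <- counts[[cat_t]] + 1L
      key <- paste0(cat_t, "/", counts[[cat_t]])
      cells[[paste0(key, "/LABEL")]] <- labels[[t]] %|% ""
      cells[[paste0(key, "/ID")]] <- t
    }
    tibble::as_tibble(cells)
  })
  df <- dplyr::bind_rows(rows)
  hd <- stringr::str_match(names(df), "^(AS|CT|B)/([0-9]+)/([A-Z]+)$")
  ord <- order(match(hd[, 2], c("AS", "CT", "B")), as.integer(hd[, 3]),
               match(hd[, 4], c("LABEL", "ID")))
  df <- df[ord]
  df[is.na(df)] <- ""
  readr::format_csv(df)
}
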