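test_that("the bundled kidney-table extract parses to typed columns", {
  tb <- builtin_fixture("table1_extract")
  expect_identical(nrow(tb$rows), 2L)
  expect_identical(ncol(tb$rows), 6L)
  expect_setequal(unique(tb$headers$category), c("AS", "CT"))
  expect_setequal(tb$headers$index[tb$headers$category == "AS"], c(4L, 4L, 5L, 5L))
})

test_that("header category indices are echoed from the header row", {
  csv <- paste("AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID,AS/3/LABEL,AS/3/ID,CT/1/LABEL,CT/1/ID",
               sep = "\n")
  tb <- parse_asctb(csv)
  expect_identical(nrow(tb$rows), 0L)
  idx <- split(tb$headers$index, tb$headers$category)
  expect_setequal(unique(idx$AS), 1:3)
  expect_identical(unique(idx$CT), 1L)
  expect_error(parse_asctb("just,a,csv\n1,2,3\n"), "header")
})

test_that("adjacency extraction yields the recorded kidney-extract triples", {
  h <- extract_triples(builtin_fixture("table1_extract"))
  tr <- tidy(h)
  expect_identical(nrow(tr), 4L)
  po <- tr[tr$predicate == "ccf_part_of", ]
  expect_setequal(po$subject, "UBERON:0001986")
  expect_setequal(po$object, c("UBERON:0009202", "UBERON:0009091"))
  li <- tr[tr$predicate == "ccf_located_in", ]
  expect_setequal(li$subject, c("CL:1001285", "CL:1001131"))
  expect_setequal(li$object, "UBERON:0001986")
  # the identifier printed with a stray space normalized to a clean CURIE
  expect_true("CL:1001131" %in% h$terms$id)
})

test_that("a row of nested structures yields one triple per adjacent pair", {
  h <- extract_triples(builtin_fixture("fig2_rows"))
  tr <- tidy(h)
  row4 <- tr[purrr::map_lgl(tr$sources, ~ 4L %in% .x$row), ]
  expect_setequal(
    paste(row4$subject, row4$object),
    c("UBERON:0001229 UBERON:0001285",   # renal corpuscle part_of nephron
      "UBERON:0001285 UBERON:0002113"))  # nephron part_of kidney
  expect_true(all(tr$predicate == "ccf_part_of"))
  # duplicated (nephron, kidney) pairs across rows merge with sources kept
  nk <- tr[tr$subject == "UBERON:0001285" & tr$object == "UBERON:0002113", ]
  expect_identical(nrow(nk), 1L)
  expect_setequal(nk$sources[[1]]$row, c(3L, 4L))
})

test_that("rows with a single term produce no triples", {
  csv <- "AS/1/LABEL,AS/1/ID\nkidney,UBERON:0002113\n"
  expect_identical(nrow(tidy(make_hierarchy(csv))), 0L)
})

test_that("blank cells are skipped so the most specific filled terms link", {
  csv <- paste(
    "AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID,AS/3/LABEL,AS/3/ID,CT/1/LABEL,CT/1/ID",
    "kidney,UBERON:0002113,,,nephron,UBERON:0001285,podocyte,CL:0000653",
    sep = "\n")
  tr <- tidy(make_hierarchy(csv))
  expect_identical(nrow(tr), 2L)
  expect_identical(tr$object[tr$predicate == "ccf_part_of"], "UBERON:0002113")
  expect_identical(tr$subject[tr$predicate == "ccf_part_of"], "UBERON:0001285")
  # located_in targets the LAST filled structure
  expect_identical(tr$object[tr$predicate == "ccf_located_in"], "UBERON:0001285")
})

test_that("cell-type chains, biomarkers and table kinds map to their predicates", {
  csv <- paste(
    "AS/1/LABEL,AS/1/ID,CT/1/LABEL,CT/1/ID,CT/2/LABEL,CT/2/ID,B/1/LABEL,B/1/ID",
    "kidney,UBERON:0002113,cell,CL:0000000,podocyte,CL:0000653,nephrin,EX:NPHS1",
    sep = "\n")
  tr <- tidy(make_hierarchy(csv))
  expect_identical(tr$predicate[tr$subject == "CL:0000653" & tr$object == "CL:0000000"],
                   "ccf_is_a")
  expect_identical(tr$predicate[tr$subject == "EX:NPHS1"], "ccf_characterizes")
  expect_identical(tr$object[tr$subject == "EX:NPHS1"], "CL:0000653")
  # first cell type is located in the last structure
  expect_identical(tr$predicate[tr$subject == "CL:0000000"], "ccf_located_in")

  vasc <- extract_triples(parse_asctb(
    "AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID\naorta,EX:a,arch,EX:b\n"),
    table_kind = "vasculature")
  expect_identical(tidy(vasc)$predicate, "ccf_branching_part_of")
})

test_that("self-pairs are flagged rather than silently dropped", {
  csv <- paste("AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID",
               "tubule,UBERON:0009773,tubule,UBERON:0009773", sep = "\n")
  tr <- tidy(make_hierarchy(csv))
  expect_identical(nrow(tr), 1L)
  expect_true(tr$self_reference)
})

test_that("unparseable identifiers become unresolved terms, not errors", {
  csv <- paste("AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID",
               "kidney,UBERON:0002113,mystery,not an id", sep = "\n")
  h <- make_hierarchy(csv)
  expect_false(h$terms$resolved[h$terms$id == "not an id"])
  expect_true(h$terms$resolved[h$terms$id == "UBERON:0002113"])
})

test_that("triple extraction is invariant under row permutation", {
  tb <- builtin_fixture("fig2_rows")
  perm <- tb
  perm$rows <- perm$rows[c(4, 2, 1, 3), ]
  a <- tidy(extract_triples(tb))
  b <- tidy(extract_triples(perm))
  key <- function(x) sort(paste(x$subject, x$predicate, x$object))
  expect_identical(key(a), key(b))
})

test_that("views flatten to one table row per root-to-leaf path", {
  rg <- saturate(builtin_fixture("kidney"))
  v <- extract_subset(rg, c("UBERON:0002113", "UBERON:0001285", "UBERON:0001229"),
                      relations = PART_OF)
  csv <- emit_table(v, root = "UBERON:0002113", relations = PART_OF)
  tb <- parse_asctb(csv)
  expect_identical(nrow(tb$rows), 1L)
  expect_identical(unname(unlist(tb$rows[1, c("AS/1/ID", "AS/2/ID", "AS/3/ID")])),
                   c("UBERON:0002113", "UBERON:0001285", "UBERON:0001229"))

  single <- extract_subset(rg, "UBERON:0002113", relations = PART_OF)
  one <- parse_asctb(emit_table(single, root = "UBERON:0002113"))
  expect_identical(nrow(one$rows), 1L)
  expect_identical(ncol(one$rows), 2L)
})

test_that("multi-parent terms appear once per path, matching path enumeration", {
  edges <- dplyr::bind_rows(
    edge_tbl("EX:l", PART_OF, "EX:root"),
    edge_tbl("EX:r", PART_OF, "EX:root"),
    edge_tbl("EX:x", PART_OF, "EX:l"),
    edge_tbl("EX:x", PART_OF, "EX:r"))
  v <- view_ontology(terms = term_tbl(c("EX:root", "EX:l", "EX:r", "EX:x")),
                     logical_edges = edges)
  csv <- emit_table(v, root = "EX:root", relations = PART_OF)
  tb <- parse_asctb(csv)
  paths <- oracle_paths(edges, "EX:root")
  expect_identical(nrow(tb$rows), length(paths))
  expect_true(all(tb$rows[["AS/3/ID"]] == "EX:x"))

  # cycle reachable from the root is an error naming its members
  cyc <- dplyr::bind_rows(edge_tbl("EX:a", PART_OF, "EX:b"),
                          edge_tbl("EX:b", PART_OF, "EX:a"))
  vc <- view_ontology(terms = term_tbl(c("EX:a", "EX:b")), logical_edges = cyc)
  expect_error(emit_table(vc, root = "EX:a"), "cycle")
  expect_error(emit_table(v, root = "EX:absent"), "root")
})

test_that("parse -> emit -> parse round-trips a tree-shaped hierarchy", {
  csv <- paste(
    "AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID,AS/3/LABEL,AS/3/ID",
    "kidney,UBERON:0002113,nephron,UBERON:0001285,renal corpuscle,UBERON:0001229",
    "kidney,UBERON:0002113,renal papilla,UBERON:0001228,,",
    sep = "\n")
  h <- make_hierarchy(csv)
  # assert the recorded triples as part_of and rebuild the table from the view
  onto <- ontology(terms = term_tbl(h$terms$id, h$terms$label, h$terms$category),
                   edges = edge_tbl(h$triples$subject, PART_OF, h$triples$object))
  v <- extract_subset(saturate(onto), h$terms$id, relations = PART_OF)
  h2 <- make_hierarchy(emit_table(v, root = "UBERON:0002113", relations = PART_OF))
  key <- function(x) sort(paste(x$triples$subject, x$triples$object))
  expect_identical(key(h2), key(h))
})
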