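kidney_rg <- saturate(builtin_fixture("kidney"))
cornea_rg <- saturate(builtin_fixture("cornea"))
endo_rg <- saturate(builtin_fixture("endothelium"))

test_that("check_pair returns the first entailed candidate in order", {
  cfg <- validation_config()
  hit <- check_pair(kidney_rg, "CL:0000653", "UBERON:0005751",
                    candidates = cfg$rules$CT_AS)
  expect_identical(hit, list(relation = PART_OF, direction = "forward"))

  # both subClassOf and part_of entailed: ordering decides
  onto <- ontology(terms = term_tbl(c("EX:a", "EX:b")),
                   edges = dplyr::bind_rows(edge_tbl("EX:a", SUBCLASS_OF, "EX:b"),
                                            edge_tbl("EX:a", PART_OF, "EX:b")))
  rg <- saturate(onto)
  expect_identical(check_pair(rg, "EX:a", "EX:b", cfg$rules$AS_AS)$relation,
                   SUBCLASS_OF)
  expect_identical(check_pair(rg, "EX:a", "EX:b", c(PART_OF, SUBCLASS_OF))$relation,
                   PART_OF)

  # property: over random orderings the first entailed candidate always wins
  pool <- c(SUBCLASS_OF, PART_OF, OVERLAPS, CONNECTED_TO)
  withr::with_seed(1L, {
    for (i in 1:20) {
      ord <- sample(pool)
      hit <- check_pair(rg, "EX:a", "EX:b", ord)
      entailed <- ord[vapply(ord, function(r) entails(rg, "EX:a", r, "EX:b"),
                             logical(1))]
      expect_identical(hit$relation, entailed[[1]])
    }
  })
})

test_that("check_pair falls through to reversed candidates, then to nothing", {
  onto <- ontology(terms = term_tbl(c("EX:as", "EX:ct")),
                   edges = edge_tbl("EX:as", HAS_PART, "EX:ct"))
  rg <- saturate(onto)
  hit <- check_pair(rg, "EX:ct", "EX:as", candidates = c(PART_OF, OVERLAPS),
                    reversed_candidates = HAS_PART)
  expect_identical(hit, list(relation = HAS_PART, direction = "reversed"))

  # the generic-endothelium pair fails every candidate and reversed candidate
  cfg <- validation_config()
  expect_null(check_pair(endo_rg, "UBERON:0001986", "UBERON:0009202",
                         candidates = cfg$rules$AS_AS,
                         reversed_candidates = HAS_PART))
  expect_error(check_pair(endo_rg, "EX:a", "EX:b", character()), "non-empty")
})

test_that("fallback suggestions find the most precise enclosing term", {
  term_set <- c("CL:0002363", "UBERON:8000001", "UBERON:0000964")
  sug <- suggest_fallback(cornea_rg, "CL:0002363", term_set, PART_OF)
  expect_identical(sug, list(relation = PART_OF, object = "UBERON:0000964"))

  # an unattached generic cell type yields no suggestion
  expect_null(suggest_fallback(cornea_rg, "CL:4033054",
                               c("CL:4033054", "UBERON:8000001", "UBERON:0000964"),
                               PART_OF))

  # minimality: nephron is chosen over kidney because nephron part_of kidney
  o <- suggest_fallback(kidney_rg, "CL:0000653",
                        c("CL:0000653", "UBERON:0002113", "UBERON:0001285"),
                        PART_OF)
  expect_identical(o$object, "UBERON:0001285")
  # brute-force minimality check over every candidate pair
  hits <- c("UBERON:0002113", "UBERON:0001285")
  for (cand in hits) {
    strictly_below <- vapply(setdiff(hits, cand), function(x)
      entails(kidney_rg, x, PART_OF, cand) || entails(kidney_rg, x, SUBCLASS_OF, cand),
      logical(1))
    if (identical(cand, o$object)) expect_false(any(strictly_below))
    else expect_true(any(strictly_below))
  }
})

test_that("hierarchy validation reproduces the endothelium error pattern", {
  h <- extract_triples(builtin_fixture("table1_extract"))
  rep <- validate_hierarchy(h, endo_rg, run_date = "2025-01-01")
  oc <- tidy(rep)
  as_as <- oc[oc$category_pair == "AS_AS", ]
  expect_identical(nrow(as_as), 2L)
  expect_true(all(as_as$status == "invalid"))
  # each limb's endothelial cell gets its limb suggested as enclosing structure
  ct_as <- oc[oc$category_pair == "CT_AS", ]
  expect_identical(ct_as$status, c("suggested", "suggested"))
  expect_setequal(ct_as$suggested_object[ct_as$subject == "CL:1001285"],
                  "UBERON:0009202")
  expect_setequal(ct_as$suggested_object[ct_as$subject == "CL:1001131"],
                  "UBERON:0009091")
  expect_identical(unname(rep$counts[c("invalid", "suggested")]), c(2L, 2L))
})

test_that("the cornea scenario flags the stroma link and suggests the cornea", {
  h <- extract_triples(builtin_fixture("cornea_rows"))
  rep <- validate_hierarchy(h, cornea_rg, run_date = "2025-01-01")
  oc <- tidy(rep)
  ker <- oc[oc$subject == "CL:0002363", ]
  expect_identical(ker$status, "suggested")
  expect_identical(ker$suggested_relation, PART_OF)
  expect_identical(ker$suggested_object, "UBERON:0000964")
  tel <- oc[oc$subject == "CL:4033054", ]
  expect_identical(tel$status, "invalid")
  # the anterior stroma itself validly sits inside the cornea
  expect_identical(oc$status[oc$subject == "UBERON:8000001"], "valid")
})

test_that("empty, fully-asserted and unresolved hierarchies behave per status", {
  empty <- make_hierarchy("AS/1/LABEL,AS/1/ID\n")
  rep0 <- validate_hierarchy(empty, kidney_rg)
  expect_identical(nrow(tidy(rep0)), 0L)
  expect_true(all(rep0$counts == 0L))

  # a hierarchy whose triples are all asserted validates wholesale
  csv <- paste(
    "AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID,CT/1/LABEL,CT/1/ID",
    "kidney,UBERON:0002113,nephron,UBERON:0001285,podocyte,CL:0000653",
    sep = "\n")
  h <- make_hierarchy(csv)
  rep <- validate_hierarchy(h, kidney_rg)
  expect_true(all(tidy(rep)$status == "valid"))
  expect_identical(tidy(rep)$matched_relation[tidy(rep)$category_pair == "AS_AS"],
                   PART_OF)

  # unmapped identifiers are reported, never guessed
  csv2 <- paste("AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID",
                "kidney,UBERON:0002113,oops,FMA:12345", sep = "\n")
  rep2 <- validate_hierarchy(make_hierarchy(csv2), kidney_rg)
  expect_identical(tidy(rep2)$status, "unresolved_term")
  expect_match(tidy(rep2)$notes, "FMA:12345")

  # biomarker links are carried through unvalidated
  csv3 <- paste("AS/1/LABEL,AS/1/ID,CT/1/LABEL,CT/1/ID,B/1/LABEL,B/1/ID",
                "kidney,UBERON:0002113,podocyte,CL:0000653,nephrin,EX:NPHS1",
                sep = "\n")
  rep3 <- validate_hierarchy(make_hierarchy(csv3), kidney_rg)
  b <- tidy(rep3)[tidy(rep3)$predicate == "ccf_characterizes", ]
  expect_identical(b$status, "skipped")
  expect_identical(b$notes, "not validated")
})

test_that("statuses are independent of triple order and counts partition", {
  h <- extract_triples(builtin_fixture("table1_extract"))
  rep <- validate_hierarchy(h, endo_rg)
  perm <- h
  perm$triples <- perm$triples[rev(seq_len(nrow(perm$triples))), ]
  rep_p <- validate_hierarchy(perm, endo_rg)
  key <- function(r) {
    oc <- tidy(r)
    sort(paste(oc$subject, oc$predicate, oc$object, oc$status))
  }
  expect_identical(key(rep), key(rep_p))
  expect_identical(sum(rep$counts), nrow(tidy(rep)))
})

test_that("every valid outcome is entailed by the redundant graph", {
  for (rg in list(kidney_rg, endo_rg, cornea_rg)) {
    h <- extract_triples(builtin_fixture("table1_extract"))
    oc <- tidy(validate_hierarchy(h, rg))
    ok <- oc[oc$status == "valid", ]
    for (i in seq_len(nrow(ok))) {
      expect_true(entails(rg, ok$subject[i], ok$matched_relation[i], ok$object[i]))
    }
    sug <- oc[oc$status == "suggested", ]
    for (i in seq_len(nrow(sug))) {
      expect_true(entails(rg, sug$subject[i], sug$suggested_relation[i],
                          sug$suggested_object[i]))
      expect_true(sug$suggested_object[i] %in% h$terms$id)
    }
  }
})

test_that("the output ontology preserves every triple and stamps validated edges", {
  h <- extract_triples(builtin_fixture("cornea_rows"))
  rep <- validate_hierarchy(h, cornea_rg, run_date = "2025-01-01")
  out <- compile_output_ontology(rep, h, cornea_rg)
  # one annotation edge per input triple, original predicate preserved
  expect_identical(nrow(out$annotation_edges), nrow(h$triples))
  expect_setequal(out$annotation_edges$source_relation,
                  unique(h$triples$predicate))
  # suggested logical edge keratocyte part_of cornea, plus the valid stroma edge
  lg <- out$logical_edges
  sug <- lg[lg$validation_status == "suggested", ]
  expect_identical(paste(sug$subject, sug$relation, sug$object),
                   paste("CL:0002363", PART_OF, "UBERON:0000964"))
  val <- lg[lg$validation_status == "validated", ]
  expect_identical(val$validation_date, "2025-01-01")
  # invalid triples contribute no logical edge
  expect_false(any(lg$subject == "CL:4033054"))

  # a report of only invalid/unresolved triples yields annotation edges only
  csv <- paste("AS/1/LABEL,AS/1/ID,AS/2/LABEL,AS/2/ID",
               "limb,UBERON:0009202,endothelium,UBERON:0001986", sep = "\n")
  h2 <- make_hierarchy(csv)
  out2 <- compile_output_ontology(validate_hierarchy(h2, endo_rg), h2, endo_rg)
  expect_identical(nrow(out2$logical_edges), 0L)
  expect_identical(nrow(out2$annotation_edges), 1L)

  # mismatched report/hierarchy is an integrity error
  expect_error(compile_output_ontology(rep, h2, cornea_rg), "match")
})

test_that("validated output round-trips through the obographs writer", {
  h <- extract_triples(builtin_fixture("cornea_rows"))
  rep <- validate_hierarchy(h, cornea_rg, run_date = "2025-01-01")
  out <- compile_output_ontology(rep, h, cornea_rg)
  json <- write_obograph(out)
  expect_identical(write_obograph(read_obograph(json)), json)
})

test_that("rule configurations load from YAML with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste(
    "rules:",
    "  AS_AS: [subClassOf, BFO:0000050]",
    "suggestion_relations:",
    "  AS_AS: [BFO:0000050]", sep = "\n"), path)
  cfg <- read_validation_config(path)
  expect_identical(cfg$rules$AS_AS, c(SUBCLASS_OF, PART_OF))
  expect_identical(cfg$rules$CT_AS, validation_config()$rules$CT_AS)
  expect_identical(cfg$reversed_rules$CT_AS, HAS_PART)
})
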