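# Independent oracles, deliberately written with base-R merge()/loops rather
# than the package's semi-naive join pipeline.

edge_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(paste(df$subject, df$relation, df$object))
}

# brute-force reflexive-transitive superproperty closure by path enumeration
oracle_superproperties <- function(schema) {
  out <- lapply(stats::setNames(schema$relations, schema$relations), function(r) r)
  repeat {
    grew <- FALSE
    for (r in names(out)) {
      for (i in seq_len(nrow(schema$sub_property_of))) {
        ch <- schema$sub_property_of$child[i]
        pa <- schema$sub_property_of$parent[i]
        if (ch %in% out[[r]] && !pa %in% out[[r]]) {
          out[[r]] <- c(out[[r]], pa)
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  lapply(out, sort)
}

# naive re-apply-all-rules-until-stable fixpoint over a plain data.frame
oracle_closure <- function(onto) {
  ed <- as.data.frame(onto$edges[onto$edges$provenance == "asserted",
                                 c("subject", "relation", "object")])
  ed <- unique(ed)
  sup <- oracle_superproperties(onto$schema)
  trans_rels <- c("subClassOf", onto$schema$transitive)
  chains <- as.data.frame(onto$schema$chains)

  compose <- function(a, b, out_rel) {
    m <- merge(a, b, by.x = "object", by.y = "subject")
    if (nrow(m) == 0L) return(NULL)
    data.frame(subject = m$subject, relation = out_rel, object = m$object.y)
  }
  repeat {
    n0 <- nrow(ed)
    new <- list()
    # property hierarchy
    for (r in unique(ed$relation)) {
      for (p in setdiff(sup[[r]], r)) {
        er <- ed[ed$relation == r, ]
        new[[length(new) + 1L]] <- data.frame(subject = er$subject,
                                              relation = p,
                                              object = er$object)
      }
    }
    # transitivity (incl. subClassOf)
    for (r in trans_rels) {
      er <- ed[ed$relation == r, ]
      if (nrow(er) > 0L) {
        er$object.y <- NULL
        new[[length(new) + 1L]] <- compose(er, er, r)
      }
    }
    # subclass propagation, both sides
    sc <- ed[ed$relation == "subClassOf", c("subject", "object")]
    op <- ed[ed$relation != "subClassOf", ]
    if (nrow(sc) > 0L && nrow(op) > 0L) {
      m1 <- merge(sc, op, by.x = "object", by.y = "subject")
      if (nrow(m1) > 0L) {
        new[[length(new) + 1L]] <- data.frame(subject = m1$subject,
                                              relation = m1$relation,
                                              object = m1$object.y)
      }
      m2 <- merge(op, sc, by.x = "object", by.y = "subject")
      if (nrow(m2) > 0L) {
        new[[length(new) + 1L]] <- data.frame(subject = m2$subject,
                                              relation = m2$relation,
                                              object = m2$object.y)
      }
    }
    # chains
    for (i in seq_len(nrow(chains))) {
      a <- ed[ed$relation == chains$r1[i], ]
      b <- ed[ed$relation == chains$r2[i], ]
      if (nrow(a) > 0L && nrow(b) > 0L) {
        new[[length(new) + 1L]] <- compose(a, b, chains$r3[i])
      }
    }
    new <- new[!vapply(new, is.null, logical(1))]
    if (length(new) > 0L) {
      ed <- unique(rbind(ed, do.call(rbind, new)[, c("subject", "relation", "object")]))
    }
    if (nrow(ed) == n0) break
  }
  ed
}

expect_closure_matches_oracle <- function(onto) {
  got <- tidy(saturate(onto))
  expect_identical(edge_key(got), edge_key(oracle_closure(onto)))
}

# all maximal root-to-leaf paths by exhaustive recursion over child lists
oracle_paths <- function(edges, root) {
  kids <- function(x) sort(unique(edges$subject[edges$object == x]))
  out <- list()
  recurse <- function(path) {
    k <- setdiff(kids(path[length(path)]), path)
    if (length(k) == 0L) out[[length(out) + 1L]] <<- path
    for (x in k) recurse(c(path, x))
  }
  recurse(root)
  out
}

make_hierarchy <- function(csv, kind = "organ", id = "test_table") {
  extract_triples(parse_asctb(csv, table_id = id), table_kind = kind)
}
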