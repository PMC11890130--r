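mk_terms <- function(...) {
  spec <- list(...)
  out <- data.frame(descriptor = if (length(spec)) names(spec) else character(0),
                    stringsAsFactors = FALSE)
  out$tree_numbers <- unname(spec)
  out$score <- rep(1, nrow(out))
  out
}

test_that("terms group by leading tree-number letter, replicated per category", {
  g <- group_terms_by_category(mk_terms(Hypertension = "C14.907.489",
                                        `Blood Pressure` = "G09.330.380.076"))
  expect_equal(names(g), c("C", "G"))
  expect_equal(g$C, "Hypertension")
  expect_equal(g$G, "Blood Pressure")

  # multi-category within one letter dedups; across letters replicates
  g2 <- group_terms_by_category(
    mk_terms(`Arthritis, Rheumatoid` = c("C05.550.114.154", "C17.300.775.099"),
             Pain = c("C23.888.592.612", "F02.830.816.444")))
  expect_equal(g2$C, c("Arthritis, Rheumatoid", "Pain"))
  expect_equal(g2$F, "Pain")

  expect_equal(length(group_terms_by_category(mk_terms())), 0L)
  expect_warning(g3 <- group_terms_by_category(
    mk_terms(Orphan = character(0))), "group X")
  expect_equal(g3$X, "Orphan")
})

test_that("mesh subquery is OR within category, AND across categories", {
  g <- group_terms_by_category(mk_terms(t1 = "C01", t2 = "C02",
                                        t3 = "G01.100"))
  q <- build_mesh_subquery(g)
  expect_equal(emit_query(q),
               "(t1[MeSH Terms] OR t2[MeSH Terms]) AND t3[MeSH Terms]")
  # singleton group emits the bare term
  expect_equal(emit_query(build_mesh_subquery(
    group_terms_by_category(mk_terms(`one term` = "C01")))),
    "\"one term\"[MeSH Terms]")
  expect_true(medfactcheck:::is_empty_query(
    build_mesh_subquery(group_terms_by_category(mk_terms()))))
})

test_that("keyphrase subquery ANDs quoted phrases without field tags", {
  expect_equal(emit_query(build_keyphrase_subquery(c("lung cancer",
                                                     "screening"))),
               "\"lung cancer\" AND screening")
  expect_equal(emit_query(build_keyphrase_subquery("copd")), "copd")
  expect_true(medfactcheck:::is_empty_query(
    build_keyphrase_subquery(character(0))))
})

test_that("final assembly ORs subqueries and drops empty markers", {
  mesh <- build_mesh_subquery(group_terms_by_category(
    mk_terms(t1 = "C01", t2 = "G01")))
  keys <- build_keyphrase_subquery(c("lung cancer", "screening"))
  expect_equal(build_final_query(list(mesh, keys)),
               paste0("(t1[MeSH Terms] AND t2[MeSH Terms])",
                      " OR (\"lung cancer\" AND screening)"))
  expect_equal(build_final_query(list(mesh, empty_query())),
               "t1[MeSH Terms] AND t2[MeSH Terms]")
  expect_error(build_final_query(list(empty_query(), empty_query())),
               "no query material")
})

test_that("emitted queries re-parse to the builder's tree with lawful operator counts", {
  set.seed(202)
  for (rep in 1:60) {
    terms <- random_term_set(sample(2:8, 1))
    phrases <- replicate(sample(0:4, 1), paste(
      sample(letters, 4, replace = TRUE), collapse = ""))
    groups <- group_terms_by_category(terms)
    subs <- list(build_mesh_subquery(groups),
                 build_keyphrase_subquery(phrases))
    final <- build_final_query(subs)
    # balanced parentheses
    expect_equal(lengths(regmatches(final, gregexpr("(", final, fixed = TRUE))),
                 lengths(regmatches(final, gregexpr(")", final, fixed = TRUE))))
    # round trip
    expect_true(query_trees_identical(parse_query(final),
                                      final_query_tree(subs)))
    # operator law on the mesh subquery alone
    mesh_str <- emit_query(subs[[1]])
    sizes <- lengths(unclass(groups))
    n_and <- lengths(regmatches(mesh_str, gregexpr(" AND ", mesh_str)))
    n_or <- lengths(regmatches(mesh_str, gregexpr(" OR ", mesh_str)))
    expect_equal(n_and, length(sizes) - 1L)
    expect_equal(n_or, sum(sizes - 1L))
  }
})

test_that("permuting input terms never changes tree shape or term multiset", {
  set.seed(303)
  for (rep in 1:20) {
    terms <- random_term_set(6)
    perm <- terms[sample(nrow(terms)), , drop = FALSE]
    q1 <- build_mesh_subquery(group_terms_by_category(terms))
    q2 <- build_mesh_subquery(group_terms_by_category(perm))
    s1 <- emit_query(q1); s2 <- emit_query(q2)
    tok <- function(s) sort(strsplit(gsub("[()]", "", s), " (AND|OR) ")[[1]])
    expect_equal(tok(s1), tok(s2))
    shape <- function(q) if (q$kind == "term") "t" else
      paste0(q$op, "(", paste(sort(vapply(q$children, function(ch)
        if (ch$kind == "term") "t" else paste0(ch$op, length(ch$children)),
        character(1))), collapse = ","), ")")
    expect_equal(shape(q1), shape(q2))
  }
})
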