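test_that("a minimal build yields one IRI per concept and one relation instance", {
  g <- minimal_graph()
  s <- ontology_stats(g)
  expect_equal(s$class_count, 3L)
  expect_equal(s$relation_count, 1L)
  expect_equal(unname(s$relation_count_by_type[["has_ADR"]]), 1L)
  expect_true(all(grepl("^ADR[0-9]{6}$", g$classes$iri)))
  expect_equal(anyDuplicated(g$classes$iri), 0L)
  expect_equal(s$max_depth, 2L)
  # subclass edges mirror vocabulary parents
  expect_equal(g$classes$parent_id[g$classes$concept_id == "P"], "S")
  # every relation instance carries a non-empty source annotation
  expect_true(all(nzchar(g$relation_instances$citation)))
})

test_that("a unit node carries its drug link plus exactly the present context", {
  v <- tiny_vocab()
  txt <- paste(
    "levofloxacin tablets", "",
    "ADVERSE REACTIONS", "Moderate nausea occurred in 2.0% of patients.",
    sep = "\n"
  )
  ex <- extract_relations(parse_insert(txt, "d1"), v)
  g <- build_ontology(ex$vocab, ex$triples, ex$units)
  un <- g$units
  expect_equal(nrow(un), 1L)
  # occurrence + severity present, mitigation and population absent:
  # outgoing links = has_ADR + has_occurrence + has_severity = 3
  links <- 1L + (un$occ_kind != "absent") + (!is.na(un$severity)) +
    (!is.na(un$mitigation_id)) + (!is.na(un$population_id))
  expect_equal(as.integer(links), 3L)
  s <- ontology_stats(g)
  expect_equal(s$unit_link_count, 3L)
  # scale classes joined the graph alongside the vocabulary concepts
  expect_equal(s$class_count, nrow(v$concepts) + 10L)
})

test_that("rebuilding from identical inputs gives byte-identical serializations", {
  corpus <- make_corpus(seed = 9, n_inserts = 4)
  g1 <- run_pipeline(corpus)$graph
  g2 <- run_pipeline(make_corpus(seed = 9, n_inserts = 4))$graph
  f1 <- withr::local_tempfile(fileext = ".ttl")
  f2 <- withr::local_tempfile(fileext = ".ttl")
  serialize_ontology(g1, f1)
  serialize_ontology(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an IRI registry pins assignments when the vocabulary grows", {
  corpus <- make_corpus(seed = 9, n_inserts = 4)
  res <- run_pipeline(corpus)
  reg <- graph_iri_registry(res$graph)
  v2 <- register_drug(res$vocab, "brand-new pills")
  g2 <- build_ontology(v2, res$triples, res$units,
                       metadata = list(label = "x", iri_registry = reg))
  reg2 <- graph_iri_registry(g2)
  expect_equal(reg2[names(reg)], reg)
  expect_equal(anyDuplicated(reg2), 0L)
  # without a registry the new concept shifts later assignments
  g3 <- build_ontology(v2, res$triples, res$units, metadata = list(label = "x"))
  expect_equal(anyDuplicated(graph_iri_registry(g3)), 0L)
})

test_that("per-dimension and per-type counts sum to the totals", {
  g <- run_pipeline(make_corpus(seed = 12, n_inserts = 6))$graph
  s <- ontology_stats(g)
  expect_equal(sum(s$class_count_by_dimension), s$class_count)
  expect_equal(sum(s$relation_count_by_type), s$relation_count)
  expect_lte(s$max_depth, 4L)
})

test_that("the quality evaluation passes a clean graph and flags each injected defect", {
  g <- run_pipeline(make_corpus(seed = 13, n_inserts = 4))$graph
  expect_equal(nrow(evaluate_ontology(g)), 0L)

  dangling <- g
  dangling$relation_instances$object_iri[1] <- "ADR999998"
  v <- evaluate_ontology(dangling)
  expect_true(any(v$rule == "dangling_edge" & v$principle == "coherence"))

  dup <- g
  i <- which(dup$classes$dimension == "AdverseDrugReaction")[1:2]
  dup$classes$label[i[2]] <- dup$classes$label[i[1]]
  v <- evaluate_ontology(dup)
  expect_true(any(v$rule == "duplicate_label" & v$principle == "clarity"))

  badiri <- g
  badiri$classes$iri[3] <- "NOT_AN_IRI"
  v <- evaluate_ontology(badiri)
  expect_true(any(v$rule == "iri_scheme_violation" & v$principle == "traceability"))

  nocite <- g
  nocite$relation_instances$citation[2] <- ""
  v <- evaluate_ontology(nocite)
  expect_true(any(v$rule == "missing_annotation" & v$principle == "traceability"))

  cyc <- g
  soc <- cyc$classes$concept_id[cyc$classes$level == "SOC"][1]
  pt <- cyc$classes$concept_id[cyc$classes$level == "PT" &
                                 cyc$classes$parent_id == soc][1]
  cyc$classes$parent_id[cyc$classes$concept_id == soc] <- pt
  v <- evaluate_ontology(cyc)
  expect_true(any(v$rule == "subclass_cycle" & v$principle == "coherence"))
})

test_that("domain/range violations are reported as coherence defects", {
  g <- minimal_graph()
  bad <- g
  # point has_ADR at the drug itself: range must be an adverse reaction
  bad$relation_instances$object_id[1] <- "D"
  bad$relation_instances$object_iri[1] <-
    bad$classes$iri[bad$classes$concept_id == "D"]
  v <- evaluate_ontology(bad)
  expect_true(any(v$rule == "domain_range_violation"))
})
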