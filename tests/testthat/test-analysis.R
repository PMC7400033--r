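test_that("the shared percentage operation reproduces the published arithmetic", {
  expect_equal(percentage(7725, 15711, 2), 49.17)
  expect_equal(percentage(4043, 7725, 2), 52.34)
  expect_equal(percentage(716, 7725, 2), 9.27)
  expect_equal(percentage(4037, 7725, 2), 52.26)
  expect_equal(percentage(141, 165, 1), 85.5)
  expect_equal(percentage(127, 165, 1), 77.0)
  expect_equal(percentage(132, 165, 1), 80.0)
  expect_equal(percentage(21, 122, 2), 17.21)
  expect_equal(percentage(221, 319, 2), 69.28)
  expect_equal(percentage(1, 3, 2), 33.33)
})

test_that("rounding is half-away-from-zero at 1 or 2 decimals only", {
  expect_equal(percentage(15, 10000, 1), 0.2)    # 0.15 rounds away from zero
  expect_equal(percentage(125, 10000, 2), 1.25)
  expect_equal(percentage(1, 8, 2), 12.5)
  expect_error(percentage(1, 0), "positive count")
  expect_error(percentage(1, 10, 3), "1 or 2")
})

test_that("the triple-type distribution covers all eight types and conserves counts", {
  v <- tiny_vocab()
  tr2 <- tibble::tibble(
    subject_id = c("D1", "D1", "D1", "D2"),
    relation = c("has_ADR", "has_ADR", "has_dose_form", "has_dose_form"),
    object_id = c("P2", "P4", "A5", "A5"),
    document_id = "d", section_index = 1L, start = 0:3, end = 4:7
  )
  g <- build_ontology(v, tr2)
  dist <- triple_type_distribution(g)
  expect_equal(nrow(dist), 8L)
  expect_equal(dist$count[dist$relation == "has_ADR"], 2L)
  expect_equal(dist$pct[dist$relation == "has_ADR"], 50.00)
  expect_equal(dist$pct[dist$relation == "has_dose_form"], 50.00)
  expect_equal(sum(dist$count), ontology_stats(g)$relation_count)
})

test_that("per-ingredient rows report drug shares against the retained totals", {
  v <- load_vocabulary(dplyr::bind_rows(
    tiny_vocab_table(),
    tibble::tibble(
      concept_id = c("D3", "D4"),
      preferred_label = c("ciprofloxacin tablets", "ciprofloxacin capsules"),
      synonyms = "", dimension = "Drug", level = "NA", parent_id = "",
      codes = "ingredient=ciprofloxacin", category = ""
    )
  ))
  tr <- tibble::tibble(
    subject_id = c("D1", "D2", "D3", "D4", "D2"),
    relation = "has_ADR",
    object_id = c("P2", "P2", "P3", "P4", "P4"),
    document_id = "d", section_index = 1L, start = 0L, end = 1L
  )
  g <- build_ontology(v, tr)
  rows <- per_ingredient_summary(g)
  lev <- rows[rows$ingredient == "levofloxacin", ]
  cip <- rows[rows$ingredient == "ciprofloxacin", ]
  expect_equal(lev$drug_pct, 25.00)   # 1 of 4 drugs
  expect_equal(cip$drug_pct, 75.00)
  expect_equal(cip$n_pairs, 4L)
  expect_true(all(rows$n_unique_adrs <= rows$n_pairs))
})

test_that("route exclusions shrink the denominator before any share is computed", {
  corpus <- make_corpus(seed = 31, n_inserts = 8)
  g <- run_pipeline(corpus)$graph
  all_rows <- per_ingredient_summary(g)
  kept <- per_ingredient_summary(
    g, exclusions = list(routes_not_in = c("oral", "intravenous"))
  )
  expect_lte(sum(kept$n_drugs), sum(all_rows$n_drugs))
  if (nrow(kept) > 0) {
    expect_equal(sum(kept$drug_pct), 100, tolerance = 0.05)
  }
})

test_that("category counting is drug-level: many ADRs in one category count once", {
  v <- tiny_vocab()
  tr <- tibble::tibble(
    subject_id = c("D1", "D1", "D1", "D2"),
    relation = "has_ADR",
    object_id = c("P3", "P4", "I2", "P2"),   # three skin ADRs for D1
    document_id = "d", section_index = 1L, start = 0L, end = 1L
  )
  g <- build_ontology(v, tr)
  rows <- category_summary(g)
  skin <- rows[rows$category == "Skin reactions", ]
  expect_equal(skin$n_drugs, 1L)
  expect_equal(skin$pct, 50.0)   # 1 of 2 drugs
  gi <- rows[rows$category == "Gastrointestinal reactions", ]
  expect_equal(gi$n_drugs, 1L)
  expect_true(all(rows$category %in% c(adr_categories(), "uncategorized")))
})

test_that("top ADRs rank by distinct drug count with alphabetical tie-breaks", {
  v <- tiny_vocab()
  tr <- tibble::tibble(
    subject_id = c("D1", "D2", "D1", "D1", "D2"),
    relation = "has_ADR",
    object_id = c("P4", "P4", "P2", "P3", "P3"),
    document_id = "d", section_index = 1L, start = 0L, end = 1L
  )
  g <- build_ontology(v, tr)
  top <- top_adrs(g, 10)
  expect_equal(top$adr[1], "itching")       # 2 drugs, ties with skin rash
  expect_equal(top$n_drugs[1:2], c(2L, 2L))
  expect_equal(top$adr[2], "skin rash")     # alphabetical tie-break
  expect_equal(top$pct[1], 100.0)
  expect_equal(nrow(top), 3L)               # n larger than distinct ADRs
  expect_equal(top$category[1], "Skin reactions")
  expect_equal(nrow(top_adrs(g, 1)), 1L)
})

test_that("the frequency/severity distribution matches the worked 4-unit example", {
  v <- tiny_vocab()
  txt <- paste(
    "levofloxacin tablets", "",
    "ADVERSE REACTIONS",
    "Nausea occurred in 2.0% of patients.",       # Common
    "Abdominal pain occurred in 5.0% of patients.", # Common
    "Skin rash occurred in 12.0% of patients.",   # VeryCommon
    "Itching may occur.",                          # absent
    sep = "\n"
  )
  ex <- extract_relations(parse_insert(txt, "d"), v)
  g <- build_ontology(ex$vocab, ex$triples, ex$units)
  fs <- freq_sev_distribution(g)
  expect_equal(fs$n_pairs, 4L)
  expect_equal(fs$n_explicit_frequency, 3L)
  expect_equal(fs$below_verycommon_n, 2L)
  expect_equal(fs$below_verycommon_pct_of_explicit, 66.67)
  expect_equal(sum(fs$frequency_buckets$count), fs$n_explicit_frequency)
  expect_equal(sum(fs$severity_buckets$count), fs$n_explicit_severity)
})

test_that("contraindicated populations rank by drug count; none yields an empty table", {
  g0 <- minimal_graph()
  expect_equal(nrow(top_contraindicated_populations(g0, 5)), 0L)
  v <- tiny_vocab()
  tr <- tibble::tibble(
    subject_id = c("D1", "D2", "D1"),
    relation = "has_contraindication",
    object_id = c("A1", "A1", "A2"),
    document_id = "d", section_index = 1L, start = 0L, end = 1L
  )
  g <- build_ontology(v, tr)
  top <- top_contraindicated_populations(g, 5)
  expect_equal(top$population[1], "pregnant women")
  expect_equal(top$n_drugs, c(2L, 1L))
})

test_that("reports are pure functions of the graph", {
  g <- run_pipeline(make_corpus(seed = 33, n_inserts = 5))$graph
  r1 <- summary_report(g)
  r2 <- summary_report(g)
  expect_identical(r1, r2)
})
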