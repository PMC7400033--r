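test_that("a minimal SOC-PT-IT chain loads and resolves through the hierarchy", {
  tbl <- tibble::tibble(
    concept_id = c("S", "P", "I"),
    preferred_label = c("gi disorders", "abdominal pain", "tummy ache"),
    synonyms = "", dimension = "AdverseDrugReaction",
    level = c("SOC", "PT", "IT"), parent_id = c("", "S", "P"),
    codes = "", category = ""
  )
  v <- load_vocabulary(tbl)
  expect_s3_class(v, "adr_vocabulary")
  expect_equal(nrow(v$concepts), 3L)
  # IT resolves to itself raw, and its PT is reachable as parent
  expect_equal(resolve_term("tummy ache", v, promote = FALSE), "I")
  expect_equal(ancestors("I", v), c("P", "S"))
})

test_that("vocabulary validation names the offending structure", {
  base <- tiny_vocab_table()
  cyc <- tibble::tibble(
    concept_id = c("A", "B"), preferred_label = c("group a", "group b"),
    synonyms = "", dimension = "Population", level = "NA",
    parent_id = c("B", "A"), codes = "", category = ""
  )
  expect_error(load_vocabulary(cyc), "cycle")

  dangling <- base
  dangling$parent_id[dangling$concept_id == "P2"] <- "GHOST"
  expect_error(load_vocabulary(dangling), "dangling")

  dup <- base
  dup$preferred_label[dup$concept_id == "P2"] <- "Abdominal Pain"
  expect_error(load_vocabulary(dup), "duplicate preferred_label")

  orphan_it <- base
  orphan_it$parent_id[orphan_it$concept_id == "I1"] <- "S1"  # IT under SOC
  expect_error(load_vocabulary(orphan_it), "IT concept")

  bad_level <- base
  bad_level$level[bad_level$concept_id == "D1"] <- "PT"
  expect_error(load_vocabulary(bad_level), "level applies only")

  bad_cat <- base
  bad_cat$category[bad_cat$concept_id == "S1"] <- "Imaginary reactions"
  expect_error(load_vocabulary(bad_cat), "18 ADR categories")
})

test_that("term resolution normalizes, promotes IT to PT, and misses cleanly", {
  v <- tiny_vocab()
  expect_equal(resolve_term("tummy ache", v), "P1")          # IT -> PT promotion
  expect_equal(resolve_term("HEADACHE", v), NULL)            # not in vocabulary
  expect_equal(resolve_term("HEADACHE", v), NULL)
  expect_equal(resolve_term("NAUSEA", v), "P2")              # case variant
  expect_equal(resolve_term("  skin   rash ", v), "P3")      # whitespace collapse
  expect_equal(resolve_term("pruritus", v), "P4")            # synonym
  expect_null(resolve_term("xyzzy", v))
})

test_that("the index has total recall on its own labels (promotion-aware)", {
  v <- load_vocabulary(make_vocabulary_fixture(seed = 2, 4, 5, 2, 6, 10)$table)
  for (i in seq_len(nrow(v$concepts))) {
    id <- v$concepts$concept_id[i]
    expected <- if (v$concepts$level[i] == "IT") v$concepts$parent_id[i] else id
    expect_equal(resolve_term(v$concepts$preferred_label[i], v,
                              dimension = v$concepts$dimension[i]), expected)
  }
})

test_that("ancestor chains are short, acyclic and rooted", {
  v <- tiny_vocab()
  expect_equal(ancestors("I1", v), c("P1", "S1"))
  expect_equal(ancestors("S1", v), character(0))
  expect_error(ancestors("GHOST", v), "unknown concept_id")
  fx <- load_vocabulary(make_vocabulary_fixture(seed = 3, 5, 4, 2, 5, 8)$table)
  for (id in fx$concepts$concept_id) {
    a <- ancestors(id, fx)
    expect_lte(length(a), 3L)
    expect_equal(anyDuplicated(a), 0L)
  }
})

test_that("category lookup inherits from the nearest categorized ancestor", {
  v <- tiny_vocab()
  expect_equal(category_of("P4", v), "Skin reactions")   # from its SOC
  expect_equal(category_of("I2", v), "Skin reactions")   # two levels up
  expect_equal(category_of("S1", v), "Gastrointestinal reactions")
  expect_error(category_of("D1", v), "AdverseDrugReaction")
  expect_length(adr_categories(), 18L)
  # a concept with no categorized ancestor
  tbl <- tibble::tibble(
    concept_id = c("S", "P"), preferred_label = c("misc disorders", "oddity"),
    synonyms = "", dimension = "AdverseDrugReaction",
    level = c("SOC", "PT"), parent_id = c("", "S"), codes = "", category = ""
  )
  expect_null(category_of("P", load_vocabulary(tbl)))
})

test_that("load, re-serialize, load is idempotent across TSV, CSV and JSON", {
  v <- load_vocabulary(make_vocabulary_fixture(seed = 4, 3, 4, 1, 5, 6)$table)
  for (ext in c(".tsv", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_vocabulary(v, f)
    v2 <- load_vocabulary(f)
    expect_equal(as.data.frame(v2$concepts), as.data.frame(v$concepts),
                 ignore_attr = TRUE)
    # second round trip is byte-stable
    f2 <- withr::local_tempfile(fileext = ext)
    write_vocabulary(v2, f2)
    expect_identical(readLines(f), readLines(f2))
  }
  fj <- withr::local_tempfile(fileext = ".json")
  tab <- tiny_vocab_table()
  jsonlite::write_json(tab, fj, dataframe = "rows")
  vj <- load_vocabulary(fj)
  expect_equal(as.data.frame(vj$concepts), as.data.frame(tiny_vocab()$concepts),
               ignore_attr = TRUE)
})

test_that("provisional drug registration preserves validity and is discoverable", {
  v <- tiny_vocab()
  v2 <- register_drug(v, "novafloxacin capsules")
  id <- attr(v2, "new_id")
  expect_equal(resolve_term("novafloxacin capsules", v2), id)
  row <- v2$concepts[v2$concepts$concept_id == id, ]
  expect_true(row$provisional)
  expect_equal(row$dimension, "Drug")
})
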