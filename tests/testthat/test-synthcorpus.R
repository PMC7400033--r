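test_that("fixture sizes follow the stated arithmetic and validate cleanly", {
  fx <- make_vocabulary_fixture(seed = 1, n_soc = 3, n_pt_per_soc = 4,
                                n_it_per_pt = 1, n_drugs = 5, n_aux = 6)
  expect_equal(nrow(fx$table), 3 + 12 + 12 + 5 + 6)
  v <- load_vocabulary(fx$table)   # passes all invariants or errors
  expect_equal(nrow(v$concepts), 38L)
  expect_equal(sum(v$concepts$dimension == "Drug"), 5L)
  expect_true(all(v$concepts$category[v$concepts$level == "SOC"] %in% adr_categories()))
})

test_that("fixture and corpus generation are deterministic under the seed", {
  f1 <- make_vocabulary_fixture(seed = 42, 4, 4, 2, 6, 10)
  f2 <- make_vocabulary_fixture(seed = 42, 4, 4, 2, 6, 10)
  expect_identical(f1$table, f2$table)
  f3 <- make_vocabulary_fixture(seed = 43, 4, 4, 2, 6, 10)
  expect_false(identical(f1$manifest$drugs, f3$manifest$drugs))

  c1 <- make_corpus(seed = 5, n_inserts = 4)
  c2 <- make_corpus(seed = 5, n_inserts = 4)
  expect_identical(c1$texts, c2$texts)
  expect_identical(c1$manifest$totals, c2$manifest$totals)
})

test_that("an empty corpus has zero totals", {
  c0 <- make_corpus(seed = 1, n_inserts = 0)
  expect_length(c0$texts, 0L)
  expect_equal(c0$manifest$totals$n_pairs, 0L)
  expect_equal(c0$manifest$totals$relation_count, 0L)
  g <- run_pipeline(c0)$graph
  expect_equal(ontology_stats(g)$relation_count, 0L)
  expect_equal(ontology_stats(g)$class_count, c0$manifest$totals$class_count)
})

test_that("manifest totals are internally consistent with the per-insert lists", {
  corpus <- make_corpus(seed = 17, n_inserts = 6)
  t <- corpus$manifest$totals
  pair_n <- sum(vapply(corpus$manifest$inserts, function(x) {
    length(unique(c(x$ar$adr_id, x$warn_ids)))
  }, integer(1)))
  expect_equal(t$n_pairs, pair_n)
  expect_equal(t$relation_count, sum(unlist(t$relation_count_by_type)))
  expect_equal(sum(unlist(t$frequency_buckets)), t$n_explicit_frequency)
  expect_equal(sum(unlist(t$severity_buckets)), t$n_explicit_severity)
})

test_that("hedge-only statements plant a pair whose context stays absent end to end", {
  corpus <- make_corpus(seed = 19, n_inserts = 8)
  hedged <- dplyr::bind_rows(lapply(corpus$manifest$inserts, function(x) {
    h <- x$ar[x$ar$hedge, c("adr_id"), drop = FALSE]
    if (nrow(h)) tibble::tibble(drug_id = x$drug_id, adr_id = h$adr_id,
                                doc = x$document_id)
  }))
  expect_gt(nrow(hedged), 0L)   # the default profile plants some
  res <- run_pipeline(corpus)
  un <- res$graph$units
  for (k in seq_len(nrow(hedged))) {
    rows <- un[un$drug_id == hedged$drug_id[k] & un$adr_id == hedged$adr_id[k] &
                 un$document_id == hedged$doc[k] &
                 un$section == "ADVERSE_REACTIONS", ]
    expect_equal(rows$occ_kind, "absent")
    expect_true(is.na(rows$severity))
    # the drug-ADR assertion itself is still present
    ri <- res$graph$relation_instances
    expect_true(any(ri$relation == "has_ADR" &
                      ri$subject_id == hedged$drug_id[k] &
                      ri$object_id == hedged$adr_id[k]))
  }
})

test_that("generated inserts round-trip through the parser to the planted sections", {
  corpus <- make_corpus(seed = 23, n_inserts = 5)
  for (j in seq_along(corpus$texts)) {
    ins <- parse_insert(corpus$texts[[j]], names(corpus$texts)[j])
    m <- corpus$manifest$inserts[[j]]
    expect_equal(ins$drug_label, m$drug_label)
    expect_true("ADVERSE_REACTIONS" %in% ins$sections$section)
    expect_true(all(ins$sections$section %in% canonical_sections()))
  }
})

test_that("corpus files written to disk reload into the same pipeline inputs", {
  dir <- withr::local_tempdir()
  corpus <- make_corpus(seed = 29, n_inserts = 3, dir = dir)
  files <- list.files(dir, pattern = "^insert-.*\\.txt$", full.names = TRUE)
  expect_length(files, 3L)
  v <- load_vocabulary(file.path(dir, "vocabulary.tsv"))
  expect_equal(nrow(v$concepts), nrow(corpus$vocab$concepts))
  txt <- paste(readLines(files[1]), collapse = "\n")
  expect_identical(txt, unname(corpus$texts[[1]]))
})
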