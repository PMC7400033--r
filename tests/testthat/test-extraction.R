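test_that("dictionary NER finds disjoint mentions in document order", {
  v <- tiny_vocab()
  m <- recognize_entities("nausea and itching were seen", v, "AdverseDrugReaction")
  expect_equal(m$concept_id, c("P2", "P4"))
  expect_equal(m$surface, c("nausea", "itching"))
  # surface equals the substring at the 0-based half-open span
  expect_equal(substr("nausea and itching were seen", m$start[2] + 1, m$end[2]),
               m$surface[2])
})

test_that("leftmost-longest wins over an embedded shorter term", {
  v <- tiny_vocab()   # has both PT "skin rash" and IT "rash"
  m <- recognize_entities("a skin rash appeared", v, "AdverseDrugReaction")
  expect_equal(nrow(m), 1L)
  expect_equal(m$surface, "skin rash")
  expect_equal(m$concept_id, "P3")
})

test_that("matches never start or end inside a longer alphanumeric word", {
  v <- tiny_vocab()
  expect_equal(nrow(recognize_entities("a brash decision", v, "AdverseDrugReaction")), 0L)
  expect_equal(nrow(recognize_entities("rashes", v, "AdverseDrugReaction")), 0L)
  m <- recognize_entities("(rash)", v, "AdverseDrugReaction")
  expect_equal(m$surface, "rash")
  expect_equal(m$concept_id, "P3")        # IT promoted to PT
  expect_equal(m$raw_concept_id, "I2")    # raw hit preserved
})

test_that("NER equals the brute-force leftmost-longest oracle on random instances", {
  for (seed in 1:30) {
    inst <- random_ner_instance(seed + 5000)
    got <- recognize_entities(inst$text, inst$vocab)
    want <- ner_oracle(inst$text, inst$vocab)
    expect_equal(got$start, want$start, info = paste("seed", seed))
    expect_equal(got$end, want$end, info = paste("seed", seed))
    expect_equal(got$raw_concept_id, want$id, info = paste("seed", seed))
  }
})

test_that("section titles drive relation extraction; every triple obeys its signature", {
  v <- tiny_vocab()
  ins <- parse_insert(tiny_insert_text(), "doc1")
  ex <- extract_relations(ins, v)
  tr <- ex$triples
  expect_true(all(c("has_ADR", "has_dose_form", "has_administration_route",
                    "has_contraindication") %in% tr$relation))
  expect_true(any(tr$relation == "has_ADR" & tr$object_id == "P2"))
  expect_true(any(tr$relation == "has_contraindication" & tr$object_id == "A1"))
  expect_true(any(tr$relation == "has_contraindication" & tr$object_id == "A4"))
  rels <- adr_relations()
  for (i in seq_len(nrow(tr))) {
    spec <- rels[rels$name == tr$relation[i], ]
    sdim <- v$concepts$dimension[match(tr$subject_id[i], v$concepts$concept_id)]
    odim <- v$concepts$dimension[match(tr$object_id[i], v$concepts$concept_id)]
    expect_equal(sdim, spec$domain_dimension)
    ok_range <- odim == spec$range_dimension ||
      (spec$name == "has_contraindication" && odim %in% c("Population", "Contraindication"))
    expect_true(ok_range)
  }
})

test_that("an insert with only unrecognized sections yields nothing", {
  txt <- "drugalin\n\nSTORAGE\nKeep away from light."
  ins <- suppressWarnings(parse_insert(txt, "doc-other"))
  ex <- extract_relations(ins, tiny_vocab())
  expect_equal(nrow(ex$triples), 0L)
  expect_equal(nrow(ex$units), 0L)
})

test_that("unknown drug labels are auto-registered, or fail when disabled", {
  v <- tiny_vocab()
  txt <- sub("levofloxacin tablets", "mystery pills", tiny_insert_text())
  ins <- parse_insert(txt, "doc-unknown")
  ex <- extract_relations(ins, v)
  expect_match(ex$drug_id, "^PROV")
  expect_true(ex$vocab$concepts$provisional[ex$vocab$concepts$concept_id == ex$drug_id])
  expect_error(
    extract_relations(ins, v, extraction_config(auto_register = FALSE)),
    "auto-registration is disabled"
  )
})

test_that("sentence context attaches frequency, severity, mitigation and population", {
  v <- tiny_vocab()
  ins <- parse_insert(tiny_insert_text(), "doc1")
  ex <- extract_relations(ins, v)
  un <- ex$units
  nausea <- un[un$adr_id == "P2", ]
  expect_equal(nausea$occurrence[[1]]$kind, "point")
  expect_equal(nausea$occurrence[[1]]$value_pct, 2.3)
  rash <- un[un$adr_id == "P3", ]
  expect_equal(rash$occurrence[[1]]$kind, "term")
  expect_equal(rash$occurrence[[1]]$term_class, "Rare")
  expect_equal(rash$mitigation_id, "A3")
  itch <- un[un$adr_id == "P4", ]   # hedge-only statement
  expect_equal(itch$occurrence[[1]]$kind, "absent")
  expect_true(is.na(itch$severity))
})

test_that("context never leaks across sentence windows", {
  v <- tiny_vocab()
  txt <- paste(
    "levofloxacin tablets", "",
    "ADVERSE REACTIONS",
    "Nausea was observed. Dizziness occurred in 4% of patients in pregnant women.",
    sep = "\n"
  )
  ins <- parse_insert(txt, "doc-local")
  un <- extract_relations(ins, v)$units
  nausea <- un[un$adr_id == "P2", ]
  expect_equal(nausea$occurrence[[1]]$kind, "absent")   # 4% is in the next sentence
  expect_true(is.na(nausea$population_id))
})

test_that("one frequency in a sentence attaches to every ADR of that sentence", {
  v <- tiny_vocab()
  txt <- paste(
    "levofloxacin tablets", "",
    "ADVERSE REACTIONS", "Nausea and itching (1%-3%).",
    sep = "\n"
  )
  un <- extract_relations(parse_insert(txt, "d"), v)$units
  expect_equal(nrow(un), 2L)
  kinds <- vapply(un$occurrence, function(o) o$kind, character(1))
  expect_equal(kinds, c("range", "range"))
})

test_that("unit identifiers are stable across identical runs", {
  v <- tiny_vocab()
  ins <- parse_insert(tiny_insert_text(), "doc1")
  u1 <- extract_relations(ins, v)$units
  u2 <- extract_relations(ins, v)$units
  expect_identical(u1$unit_id, u2$unit_id)
})
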