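test_that("CIOMS frequency classification honours the printed boundaries", {
  expect_equal(classify_frequency(0.005), "VeryRare")
  expect_equal(classify_frequency(0.01), "Rare")     # inclusive lower bound
  expect_equal(classify_frequency(15.0), "VeryCommon")
  expect_equal(classify_frequency(0.0), "VeryRare")
  expect_equal(
    classify_frequency(c(0.0099, 0.1, 0.99, 1, 9.99, 10)),
    c("VeryRare", "Uncommon", "Uncommon", "Common", "Common", "VeryCommon")
  )
  expect_error(classify_frequency(-1), "non-negative")
  expect_error(classify_frequency("x"), "numeric")
})

test_that("the five CIOMS intervals partition the percentage axis and are monotone", {
  cls <- cioms_frequency_classes()
  grid <- seq(0, 50, by = 0.005)
  containing <- vapply(grid, function(p) {
    sum(p >= cls$lower_bound & p < cls$upper_bound)
  }, numeric(1))
  expect_true(all(containing == 1))
  lab <- classify_frequency(grid)
  idx <- match(lab, cls$label)
  expect_true(all(diff(idx) >= 0))
})

test_that("frequency expressions parse into point, range, term or absent", {
  ob <- parse_frequency_expression("2.3%")
  expect_equal(ob$kind, "point")
  expect_equal(ob$value_pct, 2.3)
  expect_equal(frequency_class_of(ob), "Common")

  rg <- parse_frequency_expression("0.1%-1%")
  expect_equal(rg$kind, "range")
  expect_equal(c(rg$value_pct, rg$upper_pct), c(0.1, 1))
  # ranges classify by their upper bound
  expect_equal(frequency_class_of(rg), "Common")
  expect_equal(parse_frequency_expression("0.1% to 1%")$kind, "range")

  tm <- parse_frequency_expression("rare")
  expect_equal(tm$kind, "term")
  expect_equal(tm$term_class, "Rare")
  expect_equal(parse_frequency_expression("VERY COMMON")$term_class, "VeryCommon")

  expect_equal(parse_frequency_expression("may occur")$kind, "absent")
  expect_equal(parse_frequency_expression("occasionally reported")$kind, "absent")
  expect_equal(parse_frequency_expression("")$kind, "absent")
  expect_equal(frequency_class_of(parse_frequency_expression("gibberish")), NA_character_)
})

test_that("severity grading maps CTCAE descriptors and explicit grade tokens", {
  expect_equal(grade_severity("mild"), 1L)
  expect_equal(grade_severity("Moderate dizziness"), 2L)
  expect_equal(grade_severity("severe but not immediately life-threatening"), 3L)
  expect_equal(grade_severity("life-threatening"), 4L)
  expect_equal(grade_severity("death"), 5L)
  expect_equal(grade_severity("Grade 3"), 3L)
  expect_equal(grade_severity("grade 5 event"), 5L)
  expect_true(is.na(grade_severity("unpleasant")))
  expect_equal(nrow(ctcae_grades()), 5L)
})

test_that("IRI minting is zero-padded, bounded, injective and parseable", {
  expect_equal(mint_iri(572), "ADR000572")
  expect_equal(mint_iri(0), "ADR000000")
  expect_equal(mint_iri(999999), "ADR999999")
  expect_error(mint_iri(-1), "range")
  expect_error(mint_iri(1e6), "range")
  expect_error(mint_iri(1.5), "whole")
  idx <- c(0L, 1L, 499999L, 999999L, sample.int(999998L, 100))
  iris <- mint_iri(idx)
  expect_equal(parse_iri(iris), as.integer(idx))   # round-trip
  expect_equal(anyDuplicated(mint_iri(unique(idx))), 0L)
  expect_error(parse_iri("ADR12"), "not an ADR IRI")
})

test_that("relation labels resolve through canonical names, variants and the alias", {
  expect_equal(canonical_relation("has_population"), "ADR_occurs_in")
  expect_equal(canonical_relation("has_ADR"), "has_ADR")
  expect_equal(canonical_relation("ADR_occurs in"), "ADR_occurs_in")
  expect_equal(canonical_relation("has_mitigation method"), "has_mitigation_method")
  expect_equal(canonical_relation("HAS_DOSE_FORM"), "has_dose_form")
  expect_error(canonical_relation("causes"), "valid labels")
})

test_that("the schema manifest exposes the closed dimension and relation sets", {
  m <- schema_manifest()
  expect_length(m$dimensions, 9L)
  expect_equal(nrow(m$relations), 8L)
  expect_true(all(m$relations$domain_dimension %in% m$dimensions))
  expect_true(all(m$relations$range_dimension %in% m$dimensions))
  rel <- m$relations[m$relations$name == "has_ADR", ]
  expect_equal(c(rel$domain_dimension, rel$range_dimension),
               c("Drug", "AdverseDrugReaction"))
  f <- withr::local_tempfile(fileext = ".json")
  schema_manifest(f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$dimensions, m$dimensions)
  expect_equal(back$iri_scheme$digits, 6L)
})
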