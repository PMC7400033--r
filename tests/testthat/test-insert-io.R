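test_that("section titles normalize case-insensitively with aliases and markers", {
  expect_equal(normalize_section_title("Adverse Reactions"), "ADVERSE_REACTIONS")
  expect_equal(normalize_section_title("[ADVERSE REACTIONS]"), "ADVERSE_REACTIONS")
  expect_equal(normalize_section_title("8. CONTRAINDICATIONS"), "CONTRAINDICATIONS")
  expect_equal(normalize_section_title("STORAGE"), "OTHER")
  aliases <- c("PRECAUTIONS AND WARNINGS" = "WARNINGS_AND_PRECAUTIONS")
  expect_equal(normalize_section_title("Precautions and Warnings", aliases),
               "WARNINGS_AND_PRECAUTIONS")
  expect_equal(normalize_section_title("PRECAUTIONS AND WARNINGS"), "OTHER")
})

test_that("plain-text inserts split at header lines in document order", {
  txt <- paste(
    "drugalin tablets", "",
    "ADVERSE REACTIONS", "Nausea was observed.",
    "CONTRAINDICATIONS", "Contraindicated in infants.",
    sep = "\n"
  )
  ins <- parse_insert(txt, "doc1")
  expect_s3_class(ins, "adr_package_insert")
  expect_equal(ins$drug_label, "drugalin tablets")
  expect_equal(ins$sections$section, c("ADVERSE_REACTIONS", "CONTRAINDICATIONS"))
  expect_match(ins$sections$body[1], "Nausea")
  expect_true(nzchar(ins$source_citation))
  # char spans are ordered, non-overlapping, within the document
  expect_true(all(diff(ins$sections$start) > 0))
  expect_true(all(ins$sections$end[-nrow(ins$sections)] <= ins$sections$start[-1]))
  expect_lte(max(ins$sections$end), nchar(txt))
})

test_that("duplicate canonical sections are both retained", {
  txt <- paste(
    "drugalin", "",
    "CONTRAINDICATIONS", "Contraindicated in infants.",
    "CONTRAINDICATIONS", "Contraindicated in pregnant women.",
    sep = "\n"
  )
  ins <- parse_insert(txt, "doc-dup")
  expect_equal(ins$sections$section, c("CONTRAINDICATIONS", "CONTRAINDICATIONS"))
  expect_match(ins$sections$body[1], "infants")
  expect_match(ins$sections$body[2], "pregnant")
})

test_that("degenerate documents error or degrade to OTHER with a warning", {
  expect_error(parse_insert("   \n  ", "empty"), "empty document")
  expect_warning(
    ins <- parse_insert("drugalin\njust some prose\nmore prose", "noheader"),
    "no recognized section"
  )
  expect_equal(ins$sections$section, "OTHER")
})

test_that("parsing is lossless up to whitespace and stable through the JSON dialect", {
  corpus <- make_corpus(seed = 11, n_inserts = 3)
  squash <- function(x) gsub("[[:space:]]+", " ", trimws(x))
  for (doc_id in names(corpus$texts)) {
    txt <- corpus$texts[[doc_id]]
    ins <- parse_insert(txt, doc_id)
    recon <- paste(ins$sections$raw_title, ins$sections$body, collapse = " ")
    body_after_label <- sub("^[^\n]*\n", "", txt)
    expect_identical(squash(recon), squash(body_after_label))
    # text -> JSON -> insert equals text -> insert
    ins2 <- read_insert_json(write_insert_json(ins))
    expect_equal(ins2$sections$section, ins$sections$section)
    expect_equal(ins2$sections$body, ins$sections$body)
    expect_equal(ins2$drug_label, ins$drug_label)
    # parse is idempotent on its own serialized output
    ins3 <- read_insert_json(write_insert_json(ins2))
    expect_equal(ins3$sections, ins2$sections)
  }
})

test_that("the JSON dialect validates mandatory fields and carries unknown sections as OTHER", {
  minimal <- list(
    document_id = "j1", drug_label = "drugalin",
    sections = list(list(section = "ADVERSE_REACTIONS", body = "Nausea was observed."))
  )
  ins <- read_insert_json(jsonlite::toJSON(minimal, auto_unbox = TRUE))
  expect_equal(nrow(ins$sections), 1L)
  expect_equal(ins$sections$section, "ADVERSE_REACTIONS")

  unknown <- minimal
  unknown$sections[[1]]$section <- "SHELF LIFE"
  ins2 <- read_insert_json(jsonlite::toJSON(unknown, auto_unbox = TRUE))
  expect_equal(ins2$sections$section, "OTHER")

  broken <- minimal
  broken$drug_label <- NULL
  expect_error(read_insert_json(jsonlite::toJSON(broken, auto_unbox = TRUE)),
               "mandatory field")
})

test_that("the canonical section set is closed at six members", {
  expect_length(canonical_sections(), 6L)
  expect_true("OTHER" %in% canonical_sections())
})
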