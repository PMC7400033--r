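# Shared fixtures: a small handmade vocabulary, an insert builder, and the
# brute-force NER oracle used for equivalence testing.

tiny_vocab_table <- function() {
  tibble::tribble(
    ~concept_id, ~preferred_label, ~synonyms, ~dimension, ~level, ~parent_id, ~codes, ~category,
    "S1", "gastro-intestinal system disorders", "", "AdverseDrugReaction", "SOC", "", "SOC_code=0600", "Gastrointestinal reactions",
    "S2", "skin and appendages disorders", "", "AdverseDrugReaction", "SOC", "", "SOC_code=0100", "Skin reactions",
    "P1", "abdominal pain", "stomach ache", "AdverseDrugReaction", "PT", "S1", "ARecNO=0651", "",
    "P2", "nausea", "", "AdverseDrugReaction", "PT", "S1", "ARecNO=0663", "",
    "P3", "skin rash", "", "AdverseDrugReaction", "PT", "S2", "ARecNO=0120", "",
    "P4", "itching", "pruritus", "AdverseDrugReaction", "PT", "S2", "ARecNO=0130", "",
    "I1", "tummy ache", "", "AdverseDrugReaction", "IT", "P1", "", "",
    "I2", "rash", "", "AdverseDrugReaction", "IT", "P3", "", "",
    "D1", "levofloxacin tablets", "", "Drug", "NA", "", "ingredient=levofloxacin", "",
    "D2", "ciprofloxacin injection", "", "Drug", "NA", "", "ingredient=ciprofloxacin", "",
    "A1", "pregnant women", "", "Population", "NA", "", "", "",
    "A2", "infants", "", "Population", "NA", "", "", "",
    "A3", "discontinue the drug", "", "MitigationMethod", "NA", "", "", "",
    "A4", "quinolone allergy", "", "Contraindication", "NA", "", "", "",
    "A5", "tablet", "", "DosageForm", "NA", "", "", "",
    "A6", "oral", "", "AdministrationRoute", "NA", "", "", ""
  )
}

tiny_vocab <- function() load_vocabulary(tiny_vocab_table())

# A small two-drug insert text in the plain-text dialect.
tiny_insert_text <- function() {
  paste(
    "levofloxacin tablets",
    "",
    "ADVERSE REACTIONS",
    "Nausea occurred in 2.3% of patients.",
    "Skin rash was reported as rare; discontinue the drug.",
    "Itching may occur.",
    "",
    "DOSAGE AND ADMINISTRATION",
    "Supplied as tablet. Administered by the oral route.",
    "",
    "CONTRAINDICATIONS",
    "Contraindicated in pregnant women. Do not use in patients with quinolone allergy.",
    sep = "\n"
  )
}

# Three concepts, one has_ADR triple: the smallest useful graph.
minimal_graph <- function() {
  tbl <- tibble::tibble(
    concept_id = c("S", "P", "D"),
    preferred_label = c("gi disorders", "nausea", "drugalin"),
    synonyms = "", dimension = c("AdverseDrugReaction", "AdverseDrugReaction", "Drug"),
    level = c("SOC", "PT", "NA"), parent_id = c("", "S", ""),
    codes = "", category = c("Gastrointestinal reactions", "", "")
  )
  v <- load_vocabulary(tbl)
  tr <- tibble::tibble(
    subject_id = "D", relation = "has_ADR", object_id = "P",
    document_id = "doc1", section_index = 1L, start = 0L, end = 6L
  )
  build_ontology(v, tr, metadata = list(label = "minimal"))
}

# Brute-force leftmost-longest oracle, independent of the regex-based
# implementation: lowercase fixed-string scan over every (position, form)
# pair with explicit boundary checks, then a greedy sweep that at each
# leftmost position keeps the longest match.
ner_oracle <- function(body, vocab, dimensions = adr_dimensions()) {
  cc <- vocab$concepts[vocab$concepts$dimension %in% dimensions, ]
  forms <- data.frame(
    surface = c(cc$preferred_label, unlist(cc$synonyms)),
    id = c(cc$concept_id, rep(cc$concept_id, lengths(cc$synonyms))),
    stringsAsFactors = FALSE
  )
  forms <- forms[nzchar(forms$surface), , drop = FALSE]
  low <- tolower(body)
  n <- nchar(low)
  is_alnum <- function(pos) {
    if (pos < 1 || pos > n) return(FALSE)
    grepl("[[:alnum:]]", substr(low, pos, pos))
  }
  cand <- list()
  for (r in seq_len(nrow(forms))) {
    term <- tolower(forms$surface[r])
    w <- nchar(term)
    if (w == 0 || w > n) next
    pos <- 1L
    repeat {
      hit <- regexpr(term, substr(low, pos, n), fixed = TRUE)[1]
      if (hit == -1) break
      s <- pos + hit - 1L
      e <- s + w - 1L
      if (!is_alnum(s - 1L) && !is_alnum(e + 1L)) {
        cand[[length(cand) + 1]] <- c(start = s, end = e, row = r)
      }
      pos <- s + 1L
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(0), end = integer(0), id = character(0)))
  }
  m <- do.call(rbind, cand)
  sel <- list()
  pos <- 1L
  while (pos <= n) {
    open <- m[m[, "start"] >= pos, , drop = FALSE]
    if (nrow(open) == 0) break
    first <- min(open[, "start"])
    at <- open[open[, "start"] == first, , drop = FALSE]
    # longest; ties by PT-before-IT level then smallest concept id
    len <- at[, "end"] - at[, "start"]
    at <- at[len == max(len), , drop = FALSE]
    if (nrow(at) > 1) {
      ids <- forms$id[at[, "row"]]
      lvl <- vocab$concepts$level[match(ids, vocab$concepts$concept_id)]
      ord <- order(match(lvl, c("PT", "IT", "HLT", "SOC", "NA")), ids)
      at <- at[ord, , drop = FALSE]
    }
    sel[[length(sel) + 1]] <- at[1, ]
    pos <- at[1, "end"] + 1L
  }
  s <- do.call(rbind, sel)
  data.frame(
    start = as.integer(s[, "start"] - 1L),   # 0-based half-open, as impl
    end = as.integer(s[, "end"]),
    id = forms$id[s[, "row"]],
    stringsAsFactors = FALSE
  )
}

# Random NER instance generator for the oracle-equivalence suites.
random_ner_instance <- function(seed) {
  set.seed(seed)
  rand_token <- function() {
    paste(sample(letters, sample(2:6, 1), replace = TRUE), collapse = "")
  }
  n_terms <- sample(1:50, 1)
  terms <- unique(replicate(n_terms, {
    paste(replicate(sample(1:3, 1), rand_token()), collapse = " ")
  }))
  vocab_tbl <- tibble::tibble(
    concept_id = sprintf("T%03d", seq_along(terms)),
    preferred_label = terms,
    synonyms = "",
    dimension = "AdverseDrugReaction",
    level = "SOC",
    parent_id = "",
    codes = "", category = ""
  )
  words <- character(0)
  while (sum(nchar(words)) + length(words) < sample(50:480, 1)) {
    u <- runif(1)
    w <- if (u < 0.4) sample(terms, 1)
    else if (u < 0.5) paste0(sample(terms, 1), rand_token())  # embedded: no match
    else rand_token()
    if (runif(1) < 0.3) w <- toupper(w)
    words <- c(words, w)
  }
  text <- substr(paste(words, collapse = " "), 1, 500)
  list(vocab = load_vocabulary(vocab_tbl), text = text)
}
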