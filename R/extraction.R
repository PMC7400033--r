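# Dictionary-based named entity recognition over section bodies and
# section-title-driven relation extraction into semantic triples and
# composite drug-ADR knowledge units.

#' Extraction configuration
#'
#' @param auto_register Mint a provisional Drug concept when the insert's drug
#'   label is absent from the vocabulary (default `TRUE`).
#' @param populations_as_context When `TRUE`, mentions in
#'   USE_IN_SPECIFIC_POPULATIONS are not emitted as `has_contraindication`
#'   triples (they remain available as unit population context only).
#' @return A list of settings.
#' @export
extraction_config <- function(auto_register = TRUE, populations_as_context = FALSE) {
  list(
    auto_register = auto_register,
    populations_as_context = populations_as_context
  )
}

# Internal: regex for one vocabulary surface form — tokens joined by
# whitespace runs, guarded so no match starts or ends inside a longer
# alphanumeric word. Matching is case-insensitive.
surface_pattern <- function(surface) {
  tokens <- stringr::str_split_1(stringr::str_trim(surface), "\\s+")
  esc <- vapply(tokens, function(t) {
    paste0("\\Q", t, "\\E")
  }, character(1))
  paste0("(?<![[:alnum:]])", paste(esc, collapse = "\\s+"), "(?![[:alnum:]])")
}

#' Recognise vocabulary entities in a text
#'
#' Dictionary NER: finds occurrences of vocabulary surface forms (preferred
#' labels and synonyms) restricted to the requested class dimensions, keeping
#' leftmost-longest non-overlapping matches. Matching is case-insensitive,
#' whitespace-tolerant and token-boundary-aware: a term never matches inside
#' a longer alphanumeric word. IT-level hits are promoted to their PT parent;
#' the raw hit is preserved.
#'
#' @param body Text to scan.
#' @param vocab An `adr_vocabulary`.
#' @param dimensions Class dimensions to restrict the dictionary to.
#' @param section_index Recorded on each mention (default `NA`).
#' @return Tibble of mentions: `surface`, `concept_id` (post-promotion),
#'   `raw_concept_id`, `dimension`, `section_index`, `start`, `end`
#'   (0-based, half-open offsets into `body`).
#' @export
recognize_entities <- function(body, vocab, dimensions = adr_dimensions(),
                               section_index = NA_integer_) {
  stopifnot(inherits(vocab, "adr_vocabulary"))
  empty <- tibble::tibble(
    surface = character(0), concept_id = character(0),
    raw_concept_id = character(0), dimension = character(0),
    section_index = integer(0), start = integer(0), end = integer(0)
  )
  if (is.na(body) || !nzchar(body)) return(empty)
  cc <- vocab$concepts[vocab$concepts$dimension %in% dimensions, ]
  if (nrow(cc) == 0) return(empty)

  # every (surface form, raw concept) pair in the restricted dictionary
  forms <- tibble::tibble(
    surface = c(cc$preferred_label, unlist(cc$synonyms)),
    raw_concept_id = c(cc$concept_id, rep(cc$concept_id, lengths(cc$synonyms)))
  )
  forms <- forms[nzchar(stringr::str_trim(forms$surface)), ]

  patterns <- vapply(forms$surface, surface_pattern, character(1), USE.NAMES = FALSE)
  locs <- stringr::str_locate_all(body, stringr::regex(patterns, ignore_case = TRUE))
  hits <- lengths(locs) / 2 > 0
  if (!any(hits)) return(empty)
  cand <- tibble::tibble(
    start = unname(unlist(lapply(locs[hits], function(m) m[, 1]))) - 1L,  # to 0-based
    end = unname(unlist(lapply(locs[hits], function(m) m[, 2]))),         # half-open
    raw_concept_id = rep(forms$raw_concept_id[hits],
                         vapply(locs[hits], nrow, integer(1)))
  )

  # deterministic tie-break at equal span: PT before IT, then smallest id
  lvl <- vocab$concepts$level[match(cand$raw_concept_id, vocab$concepts$concept_id)]
  cand <- cand[order(cand$start, -(cand$end - cand$start),
                     match(lvl, c("PT", "IT", "HLT", "SOC", "NA")),
                     cand$raw_concept_id, method = "radix"), ]
  # greedy leftmost-longest non-overlapping selection
  keep <- logical(nrow(cand))
  cur_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= cur_end) {
      keep[i] <- TRUE
      cur_end <- cand$end[i]
    }
  }
  sel <- cand[keep, ]
  rows <- vocab$concepts[match(sel$raw_concept_id, vocab$concepts$concept_id), ]
  promoted <- ifelse(rows$level == "IT" & !is.na(rows$parent_id),
                     rows$parent_id, rows$concept_id)
  tibble::tibble(
    surface = stringr::str_sub(body, sel$start + 1L, sel$end),
    concept_id = promoted,
    raw_concept_id = sel$raw_concept_id,
    dimension = rows$dimension,
    section_index = section_index,
    start = sel$start,
    end = sel$end
  )
}

#' Split a text into sentence windows
#'
#' Sentences end at a full stop, exclamation or question mark (and full-width
#' equivalents). Semicolons are treated as clause separators *within* a
#' sentence window, so context written after a semicolon (a common insert
#' idiom, e.g. "rash (rare); discontinue the drug.") stays attached to the
#' ADR mention of the same sentence.
#'
#' @param text Text to split.
#' @return Tibble with `sentence`, `start`, `end` (0-based, half-open).
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(sentence = character(0), start = integer(0), end = integer(0)))
  }
  term <- stringr::str_locate_all(text, "[.!?。！？]")[[1]]
  if (nrow(term)) {
    # a period between two digits is a decimal point, not a terminator
    ch <- stringr::str_sub(text, term[, 1], term[, 1])
    before <- stringr::str_sub(text, term[, 1] - 1L, term[, 1] - 1L)
    after <- stringr::str_sub(text, term[, 1] + 1L, term[, 1] + 1L)
    decimal <- ch == "." & stringr::str_detect(before, "^[0-9]$") &
      stringr::str_detect(after, "^[0-9]$")
    term <- term[!decimal, , drop = FALSE]
  }
  bounds <- unique(c(0L, term[, 2], nchar(text)))
  bounds <- bounds[order(bounds)]
  out <- tibble::tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1]
  )
  out$sentence <- stringr::str_sub(text, out$start + 1L, out$end)
  keep <- nzchar(stringr::str_trim(out$sentence))
  out <- out[keep, c("sentence", "start", "end")]
  out
}

# Internal: an "absent" frequency observation.
absent_frequency <- function(source_text = "") {
  structure(
    list(kind = "absent", value_pct = NULL, upper_pct = NULL,
         term_class = NULL, source_text = source_text),
    class = "adr_frequency_observation"
  )
}

# Internal: empty knowledge-unit tibble (occurrence is a list column of
# frequency observations).
empty_units <- function() {
  tibble::tibble(
    unit_id = character(0), drug_id = character(0), adr_id = character(0),
    occurrence = list(), severity = integer(0),
    mitigation_id = character(0), population_id = character(0),
    document_id = character(0), section_index = integer(0),
    section = character(0), start = integer(0), end = integer(0),
    sentence = character(0)
  )
}

empty_triples <- function() {
  tibble::tibble(
    subject_id = character(0), relation = character(0), object_id = character(0),
    document_id = character(0), section_index = integer(0),
    start = integer(0), end = integer(0)
  )
}

#' Attach sentence-level context to a knowledge unit
#'
#' Populates the occurrence (via [parse_frequency_expression()]), severity
#' (via [grade_severity()]), mitigation and population (via
#' [recognize_entities()] restricted to those dimensions) of a drug-ADR
#' knowledge unit, using only the given sentence window. Fields that are
#' already explicit are never overwritten; context absent from the sentence
#' stays absent.
#'
#' @param unit One-row knowledge-unit tibble (see [extract_relations()]).
#' @param sentence The minimal sentence window containing the ADR mention.
#' @param vocab An `adr_vocabulary`.
#' @return The updated one-row unit tibble.
#' @export
attach_context <- function(unit, sentence, vocab) {
  stopifnot(nrow(unit) == 1)
  if (unit$occurrence[[1]]$kind == "absent") {
    unit$occurrence[[1]] <- parse_frequency_expression(sentence)
  }
  if (is.na(unit$severity)) {
    unit$severity <- grade_severity(sentence)
  }
  if (is.na(unit$mitigation_id)) {
    m <- recognize_entities(sentence, vocab, "MitigationMethod")
    if (nrow(m) > 0) unit$mitigation_id <- m$concept_id[1]
  }
  if (is.na(unit$population_id)) {
    p <- recognize_entities(sentence, vocab, "Population")
    if (nrow(p) > 0) unit$population_id <- p$concept_id[1]
  }
  unit
}

# Internal: section-to-relation routing table.
section_relation_plan <- function(config) {
  list(
    ADVERSE_REACTIONS = "adr",
    WARNINGS_AND_PRECAUTIONS = "adr",
    DOSAGE_AND_ADMINISTRATION = "dosage",
    CONTRAINDICATIONS = "contra",
    USE_IN_SPECIFIC_POPULATIONS = if (config$populations_as_context) "none" else "contra",
    OTHER = "none"
  )
}

#' Extract semantic triples and knowledge units from a package insert
#'
#' Relation extraction driven by section titles: ADVERSE REACTIONS and
#' WARNINGS AND PRECAUTIONS yield `has_ADR` triples plus one knowledge unit
#' per drug-ADR pair per section (context attached from each mention's
#' sentence window); DOSAGE AND ADMINISTRATION yields `has_dose_form` and
#' `has_administration_route` triples; CONTRAINDICATIONS and USE IN SPECIFIC
#' POPULATIONS yield `has_contraindication` triples to Population or
#' condition concepts; OTHER sections yield nothing.
#'
#' @param insert An `adr_package_insert`.
#' @param vocab An `adr_vocabulary`; the insert's drug label must resolve to
#'   a Drug concept, or be auto-registered (see [extraction_config()]).
#' @param config Settings from [extraction_config()].
#' @return List with `triples` (tibble), `units` (tibble), `vocab` (possibly
#'   augmented with a provisional drug concept) and `drug_id`.
#' @export
extract_relations <- function(insert, vocab, config = extraction_config()) {
  stopifnot(inherits(insert, "adr_package_insert"), inherits(vocab, "adr_vocabulary"))
  drug_id <- resolve_term(insert$drug_label, vocab, dimension = "Drug")
  if (is.null(drug_id) ||
      concept_row(vocab, drug_id)$dimension != "Drug") {
    if (!config$auto_register) {
      rlang::abort(paste0(
        "drug label '", insert$drug_label,
        "' does not resolve to a Drug concept and auto-registration is disabled"
      ))
    }
    vocab <- register_drug(vocab, insert$drug_label)
    drug_id <- attr(vocab, "new_id")
  }

  plan <- section_relation_plan(config)
  triples <- empty_triples()
  units <- empty_units()

  for (i in seq_len(nrow(insert$sections))) {
    sec <- insert$sections[i, ]
    mode <- plan[[sec$section]]
    if (mode == "none") next
    body <- sec$body

    if (mode == "adr") {
      mentions <- recognize_entities(body, vocab, "AdverseDrugReaction", i)
      if (nrow(mentions) == 0) next
      triples <- dplyr::bind_rows(triples, tibble::tibble(
        subject_id = drug_id, relation = "has_ADR",
        object_id = mentions$concept_id,
        document_id = insert$document_id, section_index = i,
        start = mentions$start, end = mentions$end
      ))
      sentences <- split_sentences(body)
      for (adr in unique(mentions$concept_id)) {
        mm <- mentions[mentions$concept_id == adr, ]
        unit <- tibble::tibble(
          unit_id = paste(drug_id, adr, insert$document_id, i, sep = "|"),
          drug_id = drug_id, adr_id = adr,
          occurrence = list(absent_frequency()),
          severity = NA_integer_,
          mitigation_id = NA_character_, population_id = NA_character_,
          document_id = insert$document_id, section_index = i,
          section = sec$section,
          start = mm$start[1], end = mm$end[1],
          sentence = NA_character_
        )
        for (k in seq_len(nrow(mm))) {
          win <- sentences[sentences$start <= mm$start[k] & sentences$end >= mm$end[k], ]
          if (nrow(win) == 0) next
          if (is.na(unit$sentence)) unit$sentence <- win$sentence[1]
          unit <- attach_context(unit, win$sentence[1], vocab)
        }
        units <- dplyr::bind_rows(units, unit)
      }
    } else if (mode == "dosage") {
      forms <- recognize_entities(body, vocab, "DosageForm", i)
      routes <- recognize_entities(body, vocab, "AdministrationRoute", i)
      if (nrow(forms) > 0) {
        triples <- dplyr::bind_rows(triples, tibble::tibble(
          subject_id = drug_id, relation = "has_dose_form",
          object_id = forms$concept_id,
          document_id = insert$document_id, section_index = i,
          start = forms$start, end = forms$end
        ))
      }
      if (nrow(routes) > 0) {
        triples <- dplyr::bind_rows(triples, tibble::tibble(
          subject_id = drug_id, relation = "has_administration_route",
          object_id = routes$concept_id,
          document_id = insert$document_id, section_index = i,
          start = routes$start, end = routes$end
        ))
      }
    } else if (mode == "contra") {
      objs <- recognize_entities(body, vocab, c("Population", "Contraindication"), i)
      if (nrow(objs) > 0) {
        triples <- dplyr::bind_rows(triples, tibble::tibble(
          subject_id = drug_id, relation = "has_contraindication",
          object_id = objs$concept_id,
          document_id = insert$document_id, section_index = i,
          start = objs$start, end = objs$end
        ))
      }
    }
  }

  list(triples = triples, units = units, vocab = vocab, drug_id = drug_id)
}
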