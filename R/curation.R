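# Machine-executable biocuration: validation findings, vagueness filtering,
# and deduplication into nonredundant triples.

#' Default hedge-word list
#'
#' Phrases that claim a frequency without stating one explicitly. The list is
#' editable configuration; these defaults cover the usual insert hedges.
#'
#' @return Character vector of hedge phrases.
#' @export
default_hedges <- function() {
  c("may", "might", "possible", "possibly", "occasionally",
    "approximately", "rarely reported")
}

# Internal: does a text span contain any hedge phrase (word-bounded,
# case-insensitive)?
contains_hedge <- function(text, hedges = default_hedges()) {
  if (is.na(text) || !nzchar(text)) return(FALSE)
  norm <- normalize_surface(text)
  any(vapply(hedges, function(h) {
    stringr::str_detect(norm, paste0("\\b\\Q", normalize_surface(h), "\\E\\b"))
  }, logical(1)))
}

#' Curation configuration
#'
#' @param hedges Hedge phrase list (see [default_hedges()]).
#' @param strict In strict mode, `warn` findings are escalated to `reject`.
#' @return A list of settings.
#' @export
curation_config <- function(hedges = default_hedges(), strict = FALSE) {
  list(hedges = hedges, strict = strict)
}

new_finding <- function(ref, rule, severity, message) {
  tibble::tibble(ref = ref, rule = rule, severity = severity, message = message)
}

#' Validate extracted units and triples against the biocuration criteria
#'
#' Two printed review criteria drive the rules: completeness (an ADVERSE
#' REACTIONS section that produced no units is suspicious) and explicitness
#' (frequency and severity must be explicit; hedged frequency claims are
#' rejected). Additionally, triples or units referencing provisional
#' (auto-registered) concepts are flagged for review.
#'
#' @param units Knowledge-unit tibble from [extract_relations()].
#' @param triples Triple tibble from [extract_relations()].
#' @param insert The source `adr_package_insert`.
#' @param vocab The (possibly augmented) `adr_vocabulary`.
#' @param config Settings from [curation_config()].
#' @return Tibble of findings: `ref`, `rule`, `severity` (`warn`/`reject`),
#'   `message`. A fully contextualised, complete extraction yields no rows.
#' @export
validate_units <- function(units, triples, insert, vocab,
                           config = curation_config()) {
  findings <- new_finding(character(0), character(0), character(0), character(0))

  ar_idx <- which(insert$sections$section == "ADVERSE_REACTIONS")
  for (i in ar_idx) {
    if (!any(units$section_index == i)) {
      findings <- dplyr::bind_rows(findings, new_finding(
        insert$document_id, "possible_missing_data", "warn",
        paste0("ADVERSE_REACTIONS section ", i, " produced zero drug-ADR units")
      ))
    }
  }

  for (k in seq_len(nrow(units))) {
    u <- units[k, ]
    no_occ <- u$occurrence[[1]]$kind == "absent"
    if (no_occ && is.na(u$severity)) {
      findings <- dplyr::bind_rows(findings, new_finding(
        u$unit_id, "no_explicit_context", "warn",
        "unit has neither explicit occurrence nor explicit severity"
      ))
    }
    if (no_occ && !is.na(u$sentence) && contains_hedge(u$sentence, config$hedges)) {
      findings <- dplyr::bind_rows(findings, new_finding(
        u$unit_id, "vague_frequency_claim", "reject",
        "source sentence hedges a frequency claim without stating one"
      ))
    }
  }

  prov_ids <- vocab$concepts$concept_id[vocab$concepts$provisional]
  if (length(prov_ids) && nrow(triples)) {
    hit <- triples$subject_id %in% prov_ids | triples$object_id %in% prov_ids
    for (k in which(hit)) {
      findings <- dplyr::bind_rows(findings, new_finding(
        paste(triples$subject_id[k], triples$relation[k], triples$object_id[k], sep = "|"),
        "provisional_concept", "warn",
        "triple references a provisional (auto-registered) concept"
      ))
    }
  }

  if (config$strict && nrow(findings)) {
    findings$severity[findings$severity == "warn"] <- "reject"
  }
  findings
}

#' Clear vague occurrence/severity context
#'
#' A unit's drug-ADR assertion is always kept; only its context is cleared.
#' When the provenance sentence of a unit's occurrence matches the hedge
#' list, the occurrence and severity fields revert to absent — a vague
#' description is not recorded.
#'
#' @param units Knowledge-unit tibble.
#' @param hedges Hedge phrase list.
#' @return The unit tibble, same rows, with vague context cleared.
#' @export
filter_vague <- function(units, hedges = default_hedges()) {
  if (nrow(units) == 0) return(units)
  for (k in seq_len(nrow(units))) {
    ob <- units$occurrence[[k]]
    src <- if (!is.null(ob$source_text) && nzchar(ob$source_text)) ob$source_text else units$sentence[k]
    if (ob$kind != "absent" && contains_hedge(src, hedges)) {
      units$occurrence[[k]] <- absent_frequency(src)
      units$severity[k] <- NA_integer_
    }
  }
  units
}

#' Deduplicate semantic triples
#'
#' The uniqueness key is (subject, relation, object) after IT-to-PT promotion
#' of both ends. The first-seen provenance is kept as primary; every
#' provenance is retained in the multiplicity map, and the sum of
#' multiplicities equals the input triple count.
#'
#' @param triples Triple tibble.
#' @param vocab Optional `adr_vocabulary` used to promote any residual
#'   IT-level ids (extraction already promotes, so this is a safety net).
#' @return List: `triples` (nonredundant, first-seen provenance, plus a
#'   `multiplicity` column), `multiplicity` (key -> count tibble),
#'   `provenances` (all input rows with their key).
#' @export
dedupe <- function(triples, vocab = NULL) {
  promote <- function(ids) {
    if (is.null(vocab)) return(ids)
    rows <- vocab$concepts[match(ids, vocab$concepts$concept_id), ]
    ifelse(!is.na(rows$level) & rows$level == "IT" & !is.na(rows$parent_id),
           rows$parent_id, ids)
  }
  t2 <- triples
  if (nrow(t2)) {
    t2$subject_id <- promote(t2$subject_id)
    t2$object_id <- promote(t2$object_id)
  }
  key <- paste(t2$subject_id, t2$relation, t2$object_id, sep = "|")
  first <- !duplicated(key)
  uniq <- t2[first, ]
  counts <- table(key)
  uniq$multiplicity <- as.integer(counts[key[first]])
  prov <- t2
  prov$key <- key
  list(
    triples = uniq,
    multiplicity = tibble::tibble(
      key = names(counts), count = as.integer(counts)
    ),
    provenances = prov
  )
}
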