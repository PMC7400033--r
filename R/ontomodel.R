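# Generic ADR ontology schema: class dimensions, relation types,
# CIOMS occurrence-frequency classes, CTCAE severity grades, IRI minting.

#' The nine class dimensions of the ADR ontology
#'
#' The ontology model has two top dimensions — ADR information and medication
#' instructions — refined into nine class dimensions. Every concept in a
#' vocabulary belongs to exactly one of them. The order returned here is the
#' canonical dimension order used for deterministic IRI assignment.
#'
#' @return Character vector of the nine dimension names.
#' @export
#' @examples
#' adr_dimensions()
adr_dimensions <- function() {
  c(
    "AdverseDrugReaction", "Occurrence", "Severity", "Population",
    "MitigationMethod", "Drug", "DosageForm", "AdministrationRoute",
    "Contraindication"
  )
}

#' The eight semantic relation types
#'
#' Each relation has a canonical name, the class dimension of its subject and
#' of its object, and whether it is a top-level drug relation or a context
#' relation attached to a drug-ADR knowledge unit. `ADR_occurs_in` is the
#' canonical name for the relation sometimes labelled `has_population`.
#'
#' @return A tibble with columns `name`, `domain_dimension`, `range_dimension`,
#'   `context` (logical: attaches to a drug-ADR pair rather than the drug).
#' @export
adr_relations <- function() {
  tibble::tribble(
    ~name,                    ~domain_dimension,     ~range_dimension,      ~context,
    "has_ADR",                "Drug",                "AdverseDrugReaction", FALSE,
    "has_occurrence",         "AdverseDrugReaction", "Occurrence",          TRUE,
    "has_severity",           "AdverseDrugReaction", "Severity",            TRUE,
    "ADR_occurs_in",          "AdverseDrugReaction", "Population",          TRUE,
    "has_mitigation_method",  "AdverseDrugReaction", "MitigationMethod",    TRUE,
    "has_dose_form",          "Drug",                "DosageForm",          FALSE,
    "has_administration_route", "Drug",              "AdministrationRoute", FALSE,
    "has_contraindication",   "Drug",                "Contraindication",    FALSE
  )
}

#' CIOMS occurrence-frequency classes
#'
#' Five classes over percentage incidence, half-open on the right:
#' Very Rare \[0, 0.01), Rare \[0.01, 0.1), Uncommon \[0.1, 1),
#' Common \[1, 10), Very Common \[10, Inf). The five intervals partition
#' the non-negative percentage axis.
#'
#' @return Tibble with `label`, `lower_bound`, `upper_bound` (percent).
#' @export
cioms_frequency_classes <- function() {
  tibble::tibble(
    label = c("VeryRare", "Rare", "Uncommon", "Common", "VeryCommon"),
    lower_bound = c(0, 0.01, 0.1, 1, 10),
    upper_bound = c(0.01, 0.1, 1, 10, Inf)
  )
}

#' CTCAE severity grades
#'
#' Grade 1 (mild) through Grade 5 (death), the standard five-level severity
#' scale for adverse events.
#'
#' @return Tibble with integer `grade` and `descriptor`.
#' @export
ctcae_grades <- function() {
  tibble::tibble(
    grade = 1:5,
    descriptor = c(
      "mild", "moderate", "severe but not immediately life-threatening",
      "life-threatening", "death"
    )
  )
}

#' Classify a percentage incidence into its CIOMS frequency class
#'
#' Lower bounds are inclusive, upper bounds exclusive, so e.g. exactly 0.01%
#' is Rare and exactly 10% is Very Common. Vectorised.
#'
#' @param pct Numeric vector of percentages (>= 0).
#' @return Character vector of class labels, a factor-ordered set
#'   VeryRare < Rare < Uncommon < Common < VeryCommon.
#' @export
#' @examples
#' classify_frequency(c(0.005, 0.01, 2.3, 15))
classify_frequency <- function(pct) {
  if (!is.numeric(pct)) rlang::abort("`pct` must be numeric")
  if (any(is.na(pct))) rlang::abort("`pct` must not contain NA")
  if (any(pct < 0)) rlang::abort("`pct` must be non-negative (a percentage)")
  cls <- cioms_frequency_classes()
  idx <- findInterval(pct, c(cls$lower_bound, Inf), left.open = FALSE)
  as.character(cls$label[idx])
}

# Internal: ordered levels for frequency class comparison.
frequency_class_levels <- function() cioms_frequency_classes()$label

#' Parse a candidate frequency expression
#'
#' Handles three explicit forms found in ADVERSE REACTIONS sections: numeric
#' percentages ("2.3%"), numeric ranges ("0.1%-1%", also en/em dash and "to"),
#' and CIOMS frequency terms ("rare", "very common"). Anything else — in
#' particular hedge-only language like "may occur" — yields kind `"absent"`.
#' Term matching is case-insensitive after Unicode NFKC normalisation.
#'
#' @param text A text span (one sentence or shorter).
#' @return A frequency observation: list with `kind` (one of `"point"`,
#'   `"range"`, `"term"`, `"absent"`), `value_pct`, `upper_pct`,
#'   `term_class` (CIOMS label for kind `"term"`), `source_text`.
#' @export
#' @examples
#' parse_frequency_expression("2.3%")
#' parse_frequency_expression("rare")
#' parse_frequency_expression("may occur")
parse_frequency_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  obs <- function(kind, value = NULL, upper = NULL, term_class = NULL) {
    structure(
      list(
        kind = kind,
        value_pct = value, upper_pct = upper,
        term_class = term_class, source_text = text
      ),
      class = "adr_frequency_observation"
    )
  }
  if (is.na(text) || !nzchar(text)) return(obs("absent"))
  # lighter normalization than for vocabulary lookup: the trailing "%" of a
  # numeric expression must survive
  norm <- stringr::str_replace_all(
    stringr::str_to_lower(stringi::stri_trans_nfkc(text)), "\\s+", " "
  )

  num <- "([0-9]+(?:\\.[0-9]+)?)"
  # range first: "0.1%-1%", "0.1-1%", "0.1% to 1%"
  range_re <- paste0(num, "\\s*%?\\s*(?:-|to)\\s*", num, "\\s*%")
  m <- stringr::str_match(norm, range_re)
  if (!is.na(m[1, 1])) {
    lo <- as.numeric(m[1, 2]); hi <- as.numeric(m[1, 3])
    if (lo <= hi) return(obs("range", value = lo, upper = hi))
  }
  m <- stringr::str_match(norm, paste0(num, "\\s*%"))
  if (!is.na(m[1, 1])) {
    v <- as.numeric(m[1, 2])
    if (v >= 0 && v <= 100) return(obs("point", value = v))
  }

  # CIOMS terms; two-word terms matched before their one-word suffixes
  terms <- c(
    "very rare" = "VeryRare", "very common" = "VeryCommon",
    "uncommon" = "Uncommon", "infrequent" = "Uncommon",
    "rare" = "Rare", "common" = "Common"
  )
  for (surface in names(terms)) {
    if (stringr::str_detect(norm, paste0("\\b", surface, "\\b"))) {
      return(obs("term", term_class = unname(terms[surface])))
    }
  }
  obs("absent")
}

#' Frequency class of an observation
#'
#' Point values classify directly; ranges classify by their upper bound
#' (conservative for safety reporting); term observations carry their class;
#' absent observations return `NA`.
#'
#' @param ob A frequency observation from [parse_frequency_expression()].
#' @return A CIOMS class label or `NA_character_`.
#' @export
frequency_class_of <- function(ob) {
  stopifnot(inherits(ob, "adr_frequency_observation"))
  switch(ob$kind,
    point = classify_frequency(ob$value_pct),
    range = classify_frequency(ob$upper_pct),
    term = ob$term_class,
    absent = NA_character_
  )
}

#' Grade a severity expression on the CTCAE scale
#'
#' Maps explicit "Grade n" tokens and the scale's descriptor words
#' (mild, moderate, severe, life-threatening, death/fatal) to grades 1-5.
#' Unmatched text returns `NA_integer_` (absent).
#'
#' @param text A text span.
#' @return Integer grade 1-5, or `NA_integer_`.
#' @export
#' @examples
#' grade_severity("mild")       # 1
#' grade_severity("Grade 3")    # 3
#' grade_severity("unpleasant") # NA
grade_severity <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(NA_integer_)
  norm <- normalize_surface(text)
  m <- stringr::str_match(norm, "\\bgrade\\s*([1-5])\\b")
  if (!is.na(m[1, 1])) return(as.integer(m[1, 2]))
  # longest phrases first: the grade-3 wording contains "life-threatening"
  words <- c(
    "severe but not immediately life-threatening" = 3L,
    "life-threatening" = 4L, "life threatening" = 4L,
    "mild" = 1L, "moderate" = 2L, "severe" = 3L,
    "death" = 5L, "fatal" = 5L
  )
  for (w in names(words)) {
    if (stringr::str_detect(norm, paste0("\\b", stringr::str_replace_all(w, "-", "\\\\-"), "\\b"))) {
      return(unname(words[w]))
    }
  }
  NA_integer_
}

#' Mint an ontology IRI
#'
#' IRIs follow the scheme "ADR" followed by six decimal digits, zero-padded,
#' so the identifier space holds exactly one million entities. Injective over
#' its domain. Vectorised.
#'
#' @param index Integer vector, each in \[0, 999999\].
#' @return Character vector of IRIs, e.g. `"ADR000572"`.
#' @export
mint_iri <- function(index) {
  if (!is.numeric(index) || any(is.na(index)) || any(index != floor(index))) {
    rlang::abort("`index` must be whole numbers")
  }
  if (any(index < 0 | index > 999999)) {
    rlang::abort("IRI index out of range [0, 999999]")
  }
  sprintf("ADR%06d", as.integer(index))
}

#' Parse an IRI back to its index
#'
#' Inverse of [mint_iri()]. Vectorised.
#'
#' @param iri Character vector of "ADR"+6-digit identifiers.
#' @return Integer vector of indices.
#' @export
parse_iri <- function(iri) {
  ok <- stringr::str_detect(iri, "^ADR[0-9]{6}$")
  if (any(!ok)) {
    rlang::abort(paste0("not an ADR IRI: ", paste(iri[!ok], collapse = ", ")))
  }
  as.integer(stringr::str_sub(iri, 4L))
}

#' Resolve a relation label to its canonical relation
#'
#' Accepts the canonical names, whitespace/underscore variants, and the
#' documented alias `has_population` (which resolves to `ADR_occurs_in`).
#' Matching is case-insensitive.
#'
#' @param name A relation label.
#' @return The canonical relation name (one of [adr_relations()]`$name`).
#' @export
#' @examples
#' canonical_relation("has_population")  # "ADR_occurs_in"
canonical_relation <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  key <- stringr::str_to_lower(stringr::str_replace_all(
    normalize_surface(name), "[\\s_]+", "_"
  ))
  rels <- adr_relations()$name
  lut <- stats::setNames(rels, stringr::str_to_lower(rels))
  lut[["has_population"]] <- "ADR_occurs_in"
  if (!key %in% names(lut)) {
    rlang::abort(paste0(
      "unknown relation '", name, "'; valid labels: ",
      paste(rels, collapse = ", "), " (alias: has_population)"
    ))
  }
  unname(lut[[key]])
}

#' Machine-readable schema manifest
#'
#' Exports the schema constants — dimensions, relations, frequency classes,
#' severity grades, the IRI scheme — as a list suitable for JSON
#' serialisation, for documentation and downstream validation.
#'
#' @param path Optional file path; if given, the manifest is written as JSON.
#' @return The manifest list, invisibly if `path` is given.
#' @export
schema_manifest <- function(path = NULL) {
  manifest <- list(
    dimensions = adr_dimensions(),
    relations = adr_relations(),
    frequency_classes = cioms_frequency_classes(),
    severity_grades = ctcae_grades(),
    iri_scheme = list(prefix = "ADR", digits = 6L, max_index = 999999L)
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
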