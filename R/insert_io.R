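# Package-insert parsing: canonical section titles, plain-text splitting,
# and the structured JSON dialect.

#' Canonical package-insert sections
#'
#' The five titled sections the extraction pipeline consumes, plus OTHER for
#' everything else.
#'
#' @return Character vector of the six canonical section names.
#' @export
canonical_sections <- function() {
  c(
    "ADVERSE_REACTIONS", "WARNINGS_AND_PRECAUTIONS",
    "DOSAGE_AND_ADMINISTRATION", "CONTRAINDICATIONS",
    "USE_IN_SPECIFIC_POPULATIONS", "OTHER"
  )
}

# Internal: strip a leading bracketed or numbered marker from a header line,
# e.g. "[ADVERSE REACTIONS]", "8. CONTRAINDICATIONS", "(4) WARNINGS".
strip_header_marker <- function(line) {
  line <- stringr::str_trim(line)
  line <- stringr::str_remove(line, "^[\\[({【]\\s*")
  line <- stringr::str_remove(line, "\\s*[\\])}】]$")
  line <- stringr::str_remove(line, "^[0-9]+[.)]?\\s+")
  line
}

#' Normalise a section title to its canonical section
#'
#' Case-insensitive match of the (marker-stripped) title against the five
#' canonical names and a configurable alias table; anything unmatched maps to
#' `OTHER`.
#'
#' @param raw Raw title text.
#' @param aliases Named character vector: alias surface -> canonical section.
#' @return A canonical section name.
#' @export
#' @examples
#' normalize_section_title("Adverse Reactions")
#' normalize_section_title("STORAGE")
normalize_section_title <- function(raw, aliases = NULL) {
  key <- normalize_surface(strip_header_marker(raw))
  canon <- setdiff(canonical_sections(), "OTHER")
  lut <- stats::setNames(canon, normalize_surface(stringr::str_replace_all(canon, "_", " ")))
  if (!is.null(aliases)) {
    stopifnot(all(aliases %in% canonical_sections()))
    lut <- c(lut, stats::setNames(unname(aliases), normalize_surface(names(aliases))))
  }
  if (key %in% names(lut)) unname(lut[[key]]) else "OTHER"
}

# Internal: construct the PackageInsert object.
new_package_insert <- function(document_id, drug_label, sections,
                               active_ingredient = NULL, generation_tag = NULL,
                               source_citation = NULL) {
  if (!nzchar(drug_label)) rlang::abort("drug_label must be non-empty")
  if (is.null(source_citation) || !nzchar(source_citation)) {
    source_citation <- paste0("document:", document_id)
  }
  structure(
    list(
      document_id = document_id,
      drug_label = drug_label,
      active_ingredient = active_ingredient,
      generation_tag = generation_tag,
      sections = sections,
      source_citation = source_citation
    ),
    class = "adr_package_insert"
  )
}

#' Parse a plain-text package insert
#'
#' Splits the document at header lines. A header is a line that, after
#' stripping an optional bracketed or numbered marker, matches a canonical
#' section title or a configured alias; a section's body runs to the next
#' header or end of file. The drug label is the first non-empty line. Text
#' before the first header (after the label line) is kept as an `OTHER`
#' section. Duplicate canonical sections are retained separately.
#'
#' @param text Document text (UTF-8), or a vector of lines.
#' @param document_id Document identifier for provenance.
#' @param aliases Optional alias table (see [normalize_section_title()]).
#' @param source_citation Citation string recorded for traceability; defaults
#'   to `"document:<document_id>"`.
#' @param active_ingredient,generation_tag Optional drug metadata (the plain
#'   text format does not carry them).
#' @return An `adr_package_insert`: `document_id`, `drug_label`, `sections`
#'   (tibble with `section`, `raw_title`, `body`, `start`, `end` — 0-based
#'   half-open character offsets into the document), `source_citation`.
#' @export
parse_insert <- function(text, document_id, aliases = NULL,
                         source_citation = NULL, active_ingredient = NULL,
                         generation_tag = NULL) {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(stringr::str_trim(text))) {
    rlang::abort("empty document")
  }
  lines <- stringr::str_split_1(text, "\n")
  # 0-based start offset of each line within the document
  starts <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]

  nonempty <- which(nzchar(stringr::str_trim(lines)))
  label_line <- nonempty[1]
  drug_label <- stringr::str_trim(lines[label_line])

  is_header <- vapply(seq_along(lines), function(i) {
    i > label_line && nzchar(stringr::str_trim(lines[i])) &&
      normalize_section_title(lines[i], aliases) != "OTHER"
  }, logical(1))
  headers <- which(is_header)

  sections <- tibble::tibble(
    section = character(0), raw_title = character(0), body = character(0),
    start = integer(0), end = integer(0)
  )
  if (length(headers) == 0) {
    body_lines <- lines[(label_line + 1):length(lines)]
    rlang::warn(paste0("no recognized section in document ", document_id))
    sections <- tibble::add_row(sections,
      section = "OTHER", raw_title = "",
      body = paste(body_lines, collapse = "\n"),
      start = if (label_line < length(lines)) starts[label_line + 1] else nchar(text),
      end = nchar(text)
    )
  } else {
    if (headers[1] > label_line + 1) {
      pre <- lines[(label_line + 1):(headers[1] - 1)]
      if (any(nzchar(stringr::str_trim(pre)))) {
        sections <- tibble::add_row(sections,
          section = "OTHER", raw_title = "",
          body = paste(pre, collapse = "\n"),
          start = starts[label_line + 1], end = starts[headers[1]]
        )
      }
    }
    bounds <- c(headers, length(lines) + 1L)
    for (k in seq_along(headers)) {
      h <- headers[k]
      body_idx <- if (h + 1 <= bounds[k + 1] - 1) (h + 1):(bounds[k + 1] - 1) else integer(0)
      end_off <- if (bounds[k + 1] > length(lines)) nchar(text) else starts[bounds[k + 1]]
      sections <- tibble::add_row(sections,
        section = normalize_section_title(lines[h], aliases),
        raw_title = stringr::str_trim(lines[h]),
        body = paste(lines[body_idx], collapse = "\n"),
        start = starts[h], end = end_off
      )
    }
  }
  new_package_insert(document_id, drug_label, sections,
                     active_ingredient = active_ingredient,
                     generation_tag = generation_tag,
                     source_citation = source_citation)
}

#' Read a package insert from its structured JSON dialect
#'
#' The JSON dialect carries `document_id`, `drug_label`, optional
#' `active_ingredient`, `generation_tag` and `source_citation`, and a
#' `sections` array of objects with `section` (canonical name or any raw
#' title), `raw_title` and `body`. Unknown section names are carried as
#' `OTHER`.
#'
#' @param doc Path to a JSON file, a JSON string, or an already-parsed list.
#' @param aliases Optional alias table applied to non-canonical section names.
#' @return An `adr_package_insert`.
#' @export
read_insert_json <- function(doc, aliases = NULL) {
  if (is.character(doc)) {
    doc <- jsonlite::fromJSON(doc, simplifyDataFrame = FALSE)
  }
  for (f in c("document_id", "drug_label", "sections")) {
    if (is.null(doc[[f]])) rlang::abort(paste0("insert JSON lacks mandatory field '", f, "'"))
  }
  secs <- doc$sections
  sections <- tibble::tibble(
    section = vapply(secs, function(s) {
      nm <- s$section %||% s$raw_title %||% ""
      if (nm %in% canonical_sections()) nm
      else normalize_section_title(nm, aliases)
    }, character(1)),
    raw_title = vapply(secs, function(s) s$raw_title %||% (s$section %||% ""), character(1)),
    body = vapply(secs, function(s) s$body %||% "", character(1)),
    start = vapply(secs, function(s) as.integer(s$start %||% NA), integer(1)),
    end = vapply(secs, function(s) as.integer(s$end %||% NA), integer(1))
  )
  new_package_insert(
    doc$document_id, doc$drug_label, sections,
    active_ingredient = doc$active_ingredient,
    generation_tag = doc$generation_tag,
    source_citation = doc$source_citation
  )
}

#' Render a package insert as its structured JSON dialect
#'
#' @param insert An `adr_package_insert`.
#' @param path Optional output path; if omitted the JSON string is returned.
#' @return The JSON string, or `path` invisibly.
#' @export
write_insert_json <- function(insert, path = NULL) {
  stopifnot(inherits(insert, "adr_package_insert"))
  obj <- list(
    document_id = insert$document_id,
    drug_label = insert$drug_label,
    active_ingredient = insert$active_ingredient,
    generation_tag = insert$generation_tag,
    source_citation = insert$source_citation,
    sections = lapply(seq_len(nrow(insert$sections)), function(i) {
      s <- insert$sections[i, ]
      list(section = s$section, raw_title = s$raw_title, body = s$body,
           start = s$start, end = s$end)
    })
  )
  obj <- obj[!vapply(obj, is.null, logical(1))]
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.adr_package_insert <- function(x, ...) {
  cat("<adr_package_insert> ", x$document_id, " — ", x$drug_label, "\n", sep = "")
  print(x$sections[, c("section", "raw_title")])
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
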