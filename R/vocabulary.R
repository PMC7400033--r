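# Controlled vocabulary (WHOART/MedDRA-style): loading, validation,
# synonym indexing, hierarchy walks, the 18-category ADR scheme.

#' Normalise a surface form for matching
#'
#' Unicode NFKC normalisation, case folding, collapse of internal whitespace,
#' strip of surrounding punctuation and whitespace. This single normaliser is
#' used everywhere a piece of text is compared with a vocabulary entry.
#'
#' @param x Character vector.
#' @return Normalised character vector.
#' @export
normalize_surface <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "\\s+", " ")
  x <- stringr::str_remove_all(x, "^[[:punct:][:space:]]+|[[:punct:][:space:]]+$")
  x
}

#' The 18 ADR categories
#'
#' The closed set of body-system categories into which adverse reactions are
#' grouped for the category summary tables. Modelled as an attribute carried
#' by SOC-level vocabulary concepts.
#'
#' @return Character vector of 18 category labels.
#' @export
adr_categories <- function() {
  c(
    "Skin reactions",
    "Nervous system reactions",
    "Immune reactions and infections",
    "Gastrointestinal reactions",
    "Generalized reactions",
    "Mental disorders",
    "Liver and gallbladder diseases",
    "Urinary diseases",
    "Musculoskeletal diseases",
    "Hematological diseases",
    "Vascular, hemorrhagic, and coagulation diseases",
    "Cardiovascular diseases",
    "Respiratory system diseases",
    "Metabolic and nutrition diseases",
    "Vision diseases",
    "Auditory, vestibular, and sensory diseases",
    "Genital organ diseases",
    "Application site reactions"
  )
}

vocab_levels <- function() c("SOC", "HLT", "PT", "IT", "NA")

# Internal: coerce the synonyms column (pipe-delimited string or list) to a
# list of character vectors.
split_synonyms <- function(x) {
  if (is.list(x)) {
    return(lapply(x, function(s) {
      s <- as.character(s)
      s[nzchar(s)]
    }))
  }
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else stringr::str_trim(stringr::str_split_1(s, stringr::fixed("|")))
  })
}

# Internal: parse "key=value;key=value" codes into a named list.
split_codes <- function(x) {
  if (is.list(x)) return(x)
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(list())
    parts <- stringr::str_split_1(s, ";")
    parts <- parts[nzchar(stringr::str_trim(parts))]
    kv <- stringr::str_split_fixed(parts, "=", 2)
    stats::setNames(as.list(stringr::str_trim(kv[, 2])), stringr::str_trim(kv[, 1]))
  })
}

#' Load and validate a controlled vocabulary
#'
#' Accepts a data frame, or a path to a TSV/CSV file (header row; synonyms
#' pipe-delimited; codes as `key=value` pairs separated by semicolons), or a
#' path to an equivalent JSON file. Expected columns: `concept_id`,
#' `preferred_label`, `synonyms`, `dimension`, `level`, `parent_id`, `codes`,
#' `category`.
#'
#' Validation enforces the vocabulary invariants: parent links form a forest
#' rooted at SOC concepts with at most four levels (IT under PT, PT under HLT
#' or SOC, HLT under SOC); `level` applies only to adverse-reaction concepts;
#' preferred labels are unique within a dimension (case-insensitive); every
#' synonym resolves through the index.
#'
#' @param table Data frame or file path.
#' @return An object of class `adr_vocabulary`: list with `concepts` (tibble)
#'   and `index` (named list: normalised surface form -> concept ids).
#' @export
load_vocabulary <- function(table) {
  if (is.character(table) && length(table) == 1) {
    table <- read_vocabulary_file(table)
  }
  stopifnot(is.data.frame(table))
  required <- c("concept_id", "preferred_label", "dimension")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    rlang::abort(paste0("vocabulary table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  n <- nrow(table)
  concepts <- tibble::tibble(
    concept_id = as.character(table$concept_id),
    preferred_label = as.character(table$preferred_label),
    synonyms = split_synonyms(if ("synonyms" %in% names(table)) table$synonyms else rep("", n)),
    dimension = as.character(table$dimension),
    level = if ("level" %in% names(table)) as.character(table$level) else rep("NA", n),
    parent_id = if ("parent_id" %in% names(table)) as.character(table$parent_id) else rep(NA_character_, n),
    codes = split_codes(if ("codes" %in% names(table)) table$codes else rep("", n)),
    category = if ("category" %in% names(table)) as.character(table$category) else rep(NA_character_, n),
    provisional = if ("provisional" %in% names(table)) as.logical(table$provisional) else rep(FALSE, n)
  )
  concepts$level[is.na(concepts$level) | !nzchar(concepts$level)] <- "NA"
  concepts$parent_id[!is.na(concepts$parent_id) & !nzchar(concepts$parent_id)] <- NA_character_
  concepts$category[!is.na(concepts$category) & !nzchar(concepts$category)] <- NA_character_

  validate_vocabulary_concepts(concepts)
  vocab <- structure(
    list(concepts = concepts, index = build_synonym_index(concepts)),
    class = "adr_vocabulary"
  )
  vocab
}

# Internal: all invariant checks; abort with the offending row on violation.
validate_vocabulary_concepts <- function(concepts) {
  if (anyDuplicated(concepts$concept_id)) {
    dup <- concepts$concept_id[duplicated(concepts$concept_id)][1]
    rlang::abort(paste0("duplicate concept_id: ", dup))
  }
  bad_dim <- !concepts$dimension %in% adr_dimensions()
  if (any(bad_dim)) {
    rlang::abort(paste0(
      "unknown dimension '", concepts$dimension[bad_dim][1],
      "' for concept ", concepts$concept_id[bad_dim][1]
    ))
  }
  bad_lvl <- !concepts$level %in% vocab_levels()
  if (any(bad_lvl)) {
    rlang::abort(paste0("unknown level for concept ", concepts$concept_id[bad_lvl][1]))
  }
  non_adr_level <- concepts$dimension != "AdverseDrugReaction" & concepts$level != "NA"
  if (any(non_adr_level)) {
    rlang::abort(paste0(
      "level applies only to AdverseDrugReaction concepts; offending row: ",
      concepts$concept_id[non_adr_level][1]
    ))
  }
  adr_no_level <- concepts$dimension == "AdverseDrugReaction" & concepts$level == "NA"
  if (any(adr_no_level)) {
    rlang::abort(paste0(
      "AdverseDrugReaction concept lacks a hierarchy level: ",
      concepts$concept_id[adr_no_level][1]
    ))
  }

  # duplicate preferred labels within a dimension (case-insensitive)
  key <- paste(concepts$dimension, normalize_surface(concepts$preferred_label), sep = "\r")
  if (anyDuplicated(key)) {
    dup_row <- which(duplicated(key))[1]
    rlang::abort(paste0(
      "duplicate preferred_label within dimension: concept ",
      concepts$concept_id[dup_row], " ('", concepts$preferred_label[dup_row], "')"
    ))
  }

  # parent resolution and hierarchy shape
  has_parent <- !is.na(concepts$parent_id)
  dangling <- has_parent & !concepts$parent_id %in% concepts$concept_id
  if (any(dangling)) {
    rlang::abort(paste0(
      "dangling parent_id '", concepts$parent_id[dangling][1],
      "' for concept ", concepts$concept_id[dangling][1]
    ))
  }
  lvl <- stats::setNames(concepts$level, concepts$concept_id)
  allowed_parent <- list(
    IT = c("PT"), PT = c("HLT", "SOC"), HLT = c("SOC"), SOC = character(0)
  )
  for (i in which(concepts$dimension == "AdverseDrugReaction")) {
    l <- concepts$level[i]; p <- concepts$parent_id[i]
    if (l == "SOC") {
      if (!is.na(p)) rlang::abort(paste0("SOC concept must be a root: ", concepts$concept_id[i]))
    } else {
      if (is.na(p)) {
        rlang::abort(paste0(l, " concept lacks a parent: ", concepts$concept_id[i]))
      }
      if (!lvl[[p]] %in% allowed_parent[[l]]) {
        rlang::abort(paste0(
          l, " concept ", concepts$concept_id[i], " has ", lvl[[p]],
          " parent; allowed: ", paste(allowed_parent[[l]], collapse = "/")
        ))
      }
    }
  }

  # cycle check over all parent links
  parent <- stats::setNames(concepts$parent_id, concepts$concept_id)
  for (id in concepts$concept_id) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) rlang::abort(paste0("cycle in parent links involving ", cur))
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (length(seen) > nrow(concepts)) rlang::abort("cycle in parent links")
    }
  }

  bad_cat <- !is.na(concepts$category) & !concepts$category %in% adr_categories()
  if (any(bad_cat)) {
    rlang::abort(paste0(
      "category '", concepts$category[bad_cat][1], "' (concept ",
      concepts$concept_id[bad_cat][1], ") is not one of the 18 ADR categories"
    ))
  }
  invisible(TRUE)
}

# Internal: normalised surface form -> character vector of concept ids.
build_synonym_index <- function(concepts) {
  surfaces <- c(
    stats::setNames(as.list(concepts$preferred_label), concepts$concept_id),
    stats::setNames(concepts$synonyms, concepts$concept_id)
  )
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(concepts))) {
    forms <- unique(normalize_surface(c(
      concepts$preferred_label[i], concepts$synonyms[[i]]
    )))
    forms <- forms[nzchar(forms)]
    for (f in forms) {
      idx[[f]] <- unique(c(if (!is.null(idx[[f]])) idx[[f]], concepts$concept_id[i]))
    }
  }
  as.list(idx)
}

# Internal: read TSV/CSV/JSON vocabulary file by extension.
read_vocabulary_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    return(tibble::as_tibble(rows))
  }
  sep <- if (ext == "csv") "," else "\t"
  utils::read.table(
    path, sep = sep, header = TRUE, quote = "\"",
    stringsAsFactors = FALSE, colClasses = "character",
    na.strings = character(0), fileEncoding = "UTF-8", comment.char = ""
  )
}

#' Write a vocabulary back to its tabular file format
#'
#' Inverse of [load_vocabulary()] for the TSV/CSV dialect: synonyms are
#' pipe-delimited, codes `key=value` semicolon-delimited.
#'
#' @param vocab An `adr_vocabulary`.
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "adr_vocabulary"))
  cc <- vocab$concepts
  out <- data.frame(
    concept_id = cc$concept_id,
    preferred_label = cc$preferred_label,
    synonyms = vapply(cc$synonyms, paste, character(1), collapse = "|"),
    dimension = cc$dimension,
    level = cc$level,
    parent_id = ifelse(is.na(cc$parent_id), "", cc$parent_id),
    codes = vapply(cc$codes, function(k) {
      if (length(k) == 0) return("")
      paste(paste0(names(k), "=", unlist(k)), collapse = ";")
    }, character(1)),
    category = ifelse(is.na(cc$category), "", cc$category),
    provisional = as.character(cc$provisional),
    stringsAsFactors = FALSE
  )
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Internal: row of the concepts tibble for an id (error if absent).
concept_row <- function(vocab, concept_id) {
  i <- match(concept_id, vocab$concepts$concept_id)
  if (is.na(i)) rlang::abort(paste0("unknown concept_id: ", concept_id))
  vocab$concepts[i, ]
}

#' Resolve a surface form to a concept
#'
#' Normalised lookup in the synonym index. IT-level hits are promoted to
#' their PT parent, the canonical reporting unit (set `promote = FALSE` to
#' keep the raw hit). When one surface maps to several concepts, resolution
#' prefers a concept in the queried `dimension`, then PT over IT level, then
#' the lexicographically smallest concept id — a deterministic tie-break.
#'
#' @param surface Text to look up.
#' @param vocab An `adr_vocabulary`.
#' @param dimension Optional dimension giving the querying context.
#' @param promote Promote IT hits to their PT parent (default `TRUE`).
#' @return A concept id, or `NULL` on a miss.
#' @export
resolve_term <- function(surface, vocab, dimension = NULL, promote = TRUE) {
  stopifnot(inherits(vocab, "adr_vocabulary"))
  ids <- vocab$index[[normalize_surface(surface)]]
  if (is.null(ids)) return(NULL)
  if (length(ids) > 1) {
    rows <- vocab$concepts[match(ids, vocab$concepts$concept_id), ]
    dim_pref <- if (!is.null(dimension)) rows$dimension != dimension else rep(FALSE, length(ids))
    lvl_pref <- match(rows$level, c("PT", "IT", "HLT", "SOC", "NA"))
    ord <- order(dim_pref, lvl_pref, ids)
    ids <- ids[ord]
  }
  id <- ids[1]
  if (promote) {
    row <- concept_row(vocab, id)
    if (row$level == "IT" && !is.na(row$parent_id)) id <- row$parent_id
  }
  id
}

#' Ancestors of a concept
#'
#' The parent chain from the immediate parent up to the root, in that order.
#' Never longer than 3 (the hierarchy has at most four levels).
#'
#' @param concept_id A concept id.
#' @param vocab An `adr_vocabulary`.
#' @return Character vector of ancestor ids (possibly empty).
#' @export
ancestors <- function(concept_id, vocab) {
  stopifnot(inherits(vocab, "adr_vocabulary"))
  row <- concept_row(vocab, concept_id)
  out <- character(0)
  cur <- row$parent_id
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- concept_row(vocab, cur)$parent_id
  }
  out
}

#' Category of an adverse-reaction concept
#'
#' Returns the concept's own category if set, otherwise the category of the
#' nearest categorised ancestor (categories are usually carried at SOC
#' level), otherwise `NULL`.
#'
#' @param concept_id Id of an AdverseDrugReaction concept.
#' @param vocab An `adr_vocabulary`.
#' @return A category label, or `NULL`.
#' @export
category_of <- function(concept_id, vocab) {
  row <- concept_row(vocab, concept_id)
  if (row$dimension != "AdverseDrugReaction") {
    rlang::abort(paste0("category_of applies to AdverseDrugReaction concepts; ",
                        concept_id, " has dimension ", row$dimension))
  }
  chain <- c(concept_id, ancestors(concept_id, vocab))
  for (id in chain) {
    cat <- concept_row(vocab, id)$category
    if (!is.na(cat)) return(cat)
  }
  NULL
}

#' Register a provisional drug concept
#'
#' Adds a Drug concept for an insert's drug label that is absent from the
#' vocabulary, flagged `provisional`, so extraction can proceed for trade
#' names that were never pre-listed.
#'
#' @param vocab An `adr_vocabulary`.
#' @param label The drug label.
#' @return The updated vocabulary, with attribute `"new_id"` set.
#' @export
register_drug <- function(vocab, label) {
  stopifnot(inherits(vocab, "adr_vocabulary"))
  existing <- suppressWarnings(as.integer(stringr::str_match(
    vocab$concepts$concept_id, "^PROV([0-9]+)$"
  )[, 2]))
  nxt <- if (all(is.na(existing))) 1L else max(existing, na.rm = TRUE) + 1L
  new_id <- sprintf("PROV%04d", nxt)
  row <- tibble::tibble(
    concept_id = new_id, preferred_label = label,
    synonyms = list(character(0)), dimension = "Drug", level = "NA",
    parent_id = NA_character_, codes = list(list()),
    category = NA_character_, provisional = TRUE
  )
  concepts <- dplyr::bind_rows(vocab$concepts, row)
  validate_vocabulary_concepts(concepts)
  out <- structure(
    list(concepts = concepts, index = build_synonym_index(concepts)),
    class = "adr_vocabulary"
  )
  attr(out, "new_id") <- new_id
  out
}

#' @export
print.adr_vocabulary <- function(x, ...) {
  cat("<adr_vocabulary> ", nrow(x$concepts), " concepts across ",
      length(unique(x$concepts$dimension)), " dimensions\n", sep = "")
  print(dplyr::count(x$concepts, .data$dimension))
  invisible(x)
}
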