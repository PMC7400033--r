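# Ontology assembly, serialization (Turtle / OWL-XML / JSON), loading,
# structural statistics, and the quality evaluation.

ADR_BASE_IRI <- "https://w3id.org/adronto/"

# Internal: the ten built-in scale concepts — five CIOMS frequency classes
# (Occurrence dimension) and five CTCAE grades (Severity dimension) — that
# occurrence/severity context links point to.
builtin_scale_concepts <- function() {
  freq <- cioms_frequency_classes()
  sev <- ctcae_grades()
  tibble::tibble(
    concept_id = c(paste0("FREQ", 1:5), paste0("SEV", 1:5)),
    preferred_label = c(
      freq$label,
      paste0("Grade ", sev$grade, " (", sev$descriptor, ")")
    ),
    synonyms = rep(list(character(0)), 10),
    dimension = c(rep("Occurrence", 5), rep("Severity", 5)),
    level = "NA",
    parent_id = NA_character_,
    codes = rep(list(list()), 10),
    category = NA_character_,
    provisional = FALSE
  )
}

# Internal: registry key for IRI pinning.
iri_key <- function(dimension, label) {
  paste(dimension, normalize_surface(label), sep = "\r")
}

#' Build the ontology graph
#'
#' Deterministic assembly of curated inputs into an ontology graph. Classes
#' are the vocabulary concepts plus the ten built-in occurrence/severity
#' scale concepts; IRIs of the form "ADR"+6 digits are assigned in ascending
#' (dimension order, case-folded label) order, or pinned by an IRI registry.
#' Subclass edges mirror vocabulary parents. Each knowledge unit becomes a
#' reified node carrying its drug link, `has_ADR`, and whichever of the four
#' context relations are present (absent context is simply not linked). Every
#' relation instance and unit carries a source-citation annotation. Context
#' relations are additionally aggregated at the merged drug-ADR pair level
#' (`pair_units`), the granularity at which relation statistics are reported.
#'
#' @param vocab An `adr_vocabulary` (possibly augmented by extraction).
#' @param triples Triple tibble, or the output of [dedupe()]; raw tibbles are
#'   deduplicated here.
#' @param units Knowledge-unit tibble from [extract_relations()] (after
#'   [filter_vague()]).
#' @param metadata List: `label` (ontology label), optional `citations`
#'   (named map document_id -> citation string), optional `drug_properties`
#'   (tibble concept_id/property/value), optional `iri_registry` (named
#'   character vector: registry key -> IRI; see [graph_iri_registry()]).
#' @return An `adr_ontology_graph`.
#' @export
build_ontology <- function(vocab, triples, units = empty_units(),
                           metadata = list()) {
  stopifnot(inherits(vocab, "adr_vocabulary"))
  if (is.data.frame(triples)) triples <- dedupe(triples, vocab)
  ded <- triples$triples

  concepts <- vocab$concepts
  # the occurrence/severity scale classes are instantiated on demand: they
  # join the graph only when knowledge units exist to point at them
  builtin <- if (nrow(units) > 0) builtin_scale_concepts() else builtin_scale_concepts()[0, ]
  have <- paste(concepts$dimension, normalize_surface(concepts$preferred_label))
  builtin <- builtin[!paste(builtin$dimension, normalize_surface(builtin$preferred_label)) %in% have, ]
  all_concepts <- dplyr::bind_rows(
    dplyr::mutate(concepts, builtin = FALSE),
    dplyr::mutate(builtin, builtin = TRUE)
  )
  if (nrow(all_concepts) > 1e6) {
    rlang::abort("IRI space exhausted: more than 10^6 classes")
  }

  ord <- order(match(all_concepts$dimension, adr_dimensions()),
               normalize_surface(all_concepts$preferred_label),
               method = "radix")
  all_concepts <- all_concepts[ord, ]
  keys <- iri_key(all_concepts$dimension, all_concepts$preferred_label)
  registry <- metadata$iri_registry
  iris <- rep(NA_character_, nrow(all_concepts))
  if (!is.null(registry)) {
    pinned <- match(keys, names(registry))
    iris[!is.na(pinned)] <- unname(registry[pinned[!is.na(pinned)]])
    used <- parse_iri(iris[!is.na(iris)])
    free <- setdiff(seq(0, nrow(all_concepts) + length(used)), used)
    iris[is.na(iris)] <- mint_iri(free[seq_len(sum(is.na(iris)))])
  } else {
    iris <- mint_iri(seq_len(nrow(all_concepts)) - 1L)
  }
  classes <- tibble::tibble(
    concept_id = all_concepts$concept_id,
    iri = iris,
    label = all_concepts$preferred_label,
    dimension = all_concepts$dimension,
    level = all_concepts$level,
    parent_id = all_concepts$parent_id,
    category = all_concepts$category,
    provisional = all_concepts$provisional,
    builtin = all_concepts$builtin
  )
  if (anyDuplicated(classes$iri)) rlang::abort("IRI registry produced duplicate IRIs")
  id2iri <- stats::setNames(classes$iri, classes$concept_id)

  cite <- function(document_id) {
    cmap <- metadata$citations
    if (!is.null(cmap) && document_id %in% names(cmap)) cmap[[document_id]]
    else paste0("document:", document_id)
  }

  rel <- tibble::tibble(
    instance_id = if (nrow(ded)) sprintf("R%07d", seq_len(nrow(ded))) else character(0),
    subject_id = ded$subject_id, relation = ded$relation, object_id = ded$object_id,
    subject_iri = unname(id2iri[ded$subject_id]),
    object_iri = unname(id2iri[ded$object_id]),
    document_id = ded$document_id, section_index = ded$section_index,
    start = ded$start, end = ded$end,
    multiplicity = if (nrow(ded)) ded$multiplicity else integer(0),
    citation = vapply(ded$document_id, cite, character(1), USE.NAMES = FALSE)
  )
  if (any(is.na(rel$subject_iri) | is.na(rel$object_iri))) {
    rlang::abort("relation instance references a concept absent from the vocabulary")
  }

  un <- flatten_units(units)
  un$citation <- vapply(un$document_id, cite, character(1), USE.NAMES = FALSE)

  dp_codes <- purrr::map_dfr(seq_len(nrow(concepts)), function(i) {
    k <- concepts$codes[[i]]
    if (length(k) == 0) return(NULL)
    tibble::tibble(
      concept_id = concepts$concept_id[i],
      property = names(k),
      value = as.character(unlist(k))
    )
  })
  dp <- dplyr::bind_rows(
    tibble::tibble(concept_id = character(0), property = character(0), value = character(0)),
    dp_codes,
    metadata$drug_properties
  )
  dp <- dp[order(dp$concept_id, dp$property, dp$value, method = "radix"), ]

  graph <- structure(
    list(
      metadata = list(label = metadata$label %||% "ADR ontology"),
      classes = classes,
      relation_instances = rel,
      units = un,
      data_properties = tibble::as_tibble(dp)
    ),
    class = "adr_ontology_graph"
  )
  graph
}

# Internal: flatten the occurrence list column of a unit tibble into scalar
# columns (kind, value, upper, CIOMS class), ordered by provenance.
flatten_units <- function(units) {
  if (nrow(units) == 0) {
    return(tibble::tibble(
      unit_id = character(0), drug_id = character(0), adr_id = character(0),
      occ_kind = character(0), occ_value_pct = numeric(0), occ_upper_pct = numeric(0),
      occ_class = character(0), severity = integer(0),
      mitigation_id = character(0), population_id = character(0),
      document_id = character(0), section_index = integer(0),
      section = character(0), citation = character(0)
    ))
  }
  obs <- units$occurrence
  out <- tibble::tibble(
    unit_id = units$unit_id, drug_id = units$drug_id, adr_id = units$adr_id,
    occ_kind = vapply(obs, function(o) o$kind, character(1)),
    occ_value_pct = vapply(obs, function(o) o$value_pct %||% NA_real_, numeric(1)),
    occ_upper_pct = vapply(obs, function(o) o$upper_pct %||% NA_real_, numeric(1)),
    occ_class = vapply(obs, function(o) {
      cls <- frequency_class_of(o)
      if (is.na(cls)) NA_character_ else cls
    }, character(1)),
    severity = units$severity,
    mitigation_id = units$mitigation_id, population_id = units$population_id,
    document_id = units$document_id, section_index = units$section_index,
    section = units$section,
    citation = NA_character_
  )
  out[order(out$document_id, out$section_index, out$unit_id, method = "radix"), ]
}

#' Merged drug-ADR pair view of the knowledge units
#'
#' Context relations are reported once per deduplicated drug-ADR pair: for a
#' pair asserted in several sections, the first explicit occurrence,
#' severity, mitigation and population (in provenance order) win.
#'
#' @param graph An `adr_ontology_graph`.
#' @return Tibble with one row per (drug_id, adr_id) pair.
#' @export
pair_units <- function(graph) {
  un <- graph$units
  if (nrow(un) == 0) return(un[, setdiff(names(un), c("unit_id", "section_index", "section"))])
  un %>%
    dplyr::group_by(.data$drug_id, .data$adr_id) %>%
    dplyr::summarise(
      occ_kind = first_explicit(.data$occ_kind, .data$occ_kind != "absent", "absent"),
      occ_value_pct = first_explicit(.data$occ_value_pct, !is.na(.data$occ_value_pct), NA_real_),
      occ_upper_pct = first_explicit(.data$occ_upper_pct, !is.na(.data$occ_upper_pct), NA_real_),
      occ_class = first_explicit(.data$occ_class, !is.na(.data$occ_class), NA_character_),
      severity = first_explicit(.data$severity, !is.na(.data$severity), NA_integer_),
      mitigation_id = first_explicit(.data$mitigation_id, !is.na(.data$mitigation_id), NA_character_),
      population_id = first_explicit(.data$population_id, !is.na(.data$population_id), NA_character_),
      document_id = .data$document_id[1],
      citation = .data$citation[1],
      .groups = "drop"
    )
}

first_explicit <- function(x, explicit, default) {
  i <- which(explicit)
  if (length(i)) x[i[1]] else default
}

#' Extract the IRI registry of a graph
#'
#' A named character vector mapping (dimension, normalised label) keys to
#' IRIs. Supplying it as `metadata$iri_registry` to a later
#' [build_ontology()] pins existing assignments so that adding concepts
#' never changes established IRIs.
#'
#' @param graph An `adr_ontology_graph`.
#' @return Named character vector.
#' @export
graph_iri_registry <- function(graph) {
  stats::setNames(graph$classes$iri, iri_key(graph$classes$dimension, graph$classes$label))
}

#' Structural statistics of an ontology graph
#'
#' Class counts (total and per dimension), relation-instance counts (total
#' and per type; the four context relations counted once per merged drug-ADR
#' pair), raw unit-node and unit-link counts reported separately, and the
#' maximum class hierarchy depth (at most 4).
#'
#' @param graph An `adr_ontology_graph`.
#' @return List with `class_count`, `class_count_by_dimension`,
#'   `relation_count`, `relation_count_by_type`, `unit_node_count`,
#'   `unit_link_count`, `max_depth`.
#' @export
ontology_stats <- function(graph) {
  cls <- graph$classes
  by_dim <- table(factor(cls$dimension, levels = adr_dimensions()))
  parent <- stats::setNames(cls$parent_id, cls$concept_id)
  depth <- vapply(cls$concept_id, function(id) {
    d <- 1L
    cur <- parent[[id]]
    while (!is.na(cur) && d <= length(parent)) {
      d <- d + 1L
      cur <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
    }
    d
  }, integer(1))

  pu <- pair_units(graph)
  top <- table(factor(graph$relation_instances$relation, levels = adr_relations()$name))
  by_type <- stats::setNames(as.integer(top), names(top))
  if (nrow(pu)) {
    by_type[["has_occurrence"]] <- sum(pu$occ_kind != "absent")
    by_type[["has_severity"]] <- sum(!is.na(pu$severity))
    by_type[["has_mitigation_method"]] <- sum(!is.na(pu$mitigation_id))
    by_type[["ADR_occurs_in"]] <- sum(!is.na(pu$population_id))
  }
  unit_links <- if (nrow(graph$units)) {
    nrow(graph$units) +                                  # has_ADR link per unit node
      sum(graph$units$occ_kind != "absent") +
      sum(!is.na(graph$units$severity)) +
      sum(!is.na(graph$units$mitigation_id)) +
      sum(!is.na(graph$units$population_id))
  } else 0L

  list(
    class_count = nrow(cls),
    class_count_by_dimension = stats::setNames(as.integer(by_dim), names(by_dim)),
    relation_count = sum(by_type),
    relation_count_by_type = by_type,
    unit_node_count = nrow(graph$units),
    unit_link_count = as.integer(unit_links),
    max_depth = if (nrow(cls)) max(depth) else 0L
  )
}

#' Evaluate an ontology graph against the design principles
#'
#' Clarity: preferred labels unique within a dimension. Coherence: no
#' subclass cycles, no dangling subclass or relation edges, every relation
#' instance conforms to its type's domain and range. Traceability (minimal
#' encoding bias): every class IRI matches the "ADR"+6-digit scheme and
#' every relation instance and unit carries a non-empty source annotation.
#'
#' @param graph An `adr_ontology_graph`.
#' @return Tibble of violations (`principle`, `rule`, `ref`, `message`);
#'   empty for a clean graph.
#' @export
evaluate_ontology <- function(graph) {
  v <- tibble::tibble(principle = character(0), rule = character(0),
                      ref = character(0), message = character(0))
  add <- function(principle, rule, ref, message) {
    dplyr::bind_rows(v, tibble::tibble(
      principle = principle, rule = rule, ref = ref, message = message
    ))
  }
  cls <- graph$classes

  key <- paste(cls$dimension, normalize_surface(cls$label), sep = "\r")
  for (i in which(duplicated(key))) {
    v <- add("clarity", "duplicate_label", cls$iri[i],
             paste0("label '", cls$label[i], "' duplicated within ", cls$dimension[i]))
  }

  parent <- stats::setNames(cls$parent_id, cls$concept_id)
  for (i in seq_len(nrow(cls))) {
    p <- cls$parent_id[i]
    if (!is.na(p) && !p %in% cls$concept_id) {
      v <- add("coherence", "dangling_subclass_edge", cls$iri[i],
               paste0("parent '", p, "' is not a class"))
    }
  }
  for (id in cls$concept_id) {
    seen <- character(0); cur <- id
    repeat {
      nxt <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
      if (is.na(nxt)) break
      if (nxt %in% c(seen, cur)) {
        v <- add("coherence", "subclass_cycle", id, "cycle in subclass hierarchy")
        break
      }
      seen <- c(seen, cur); cur <- nxt
      if (length(seen) > nrow(cls)) break
    }
  }
  v <- v[!duplicated(v), ]

  rels <- adr_relations()
  iri2dim <- stats::setNames(cls$dimension, cls$iri)
  ri <- graph$relation_instances
  for (i in seq_len(nrow(ri))) {
    sdim <- iri2dim[ri$subject_iri[i]]
    odim <- iri2dim[ri$object_iri[i]]
    if (is.na(sdim) || is.na(odim)) {
      v <- add("coherence", "dangling_edge", ri$instance_id[i],
               "relation instance references a missing class IRI")
      next
    }
    spec <- rels[rels$name == ri$relation[i], ]
    if (nrow(spec) == 0) {
      v <- add("coherence", "unknown_relation", ri$instance_id[i],
               paste0("relation '", ri$relation[i], "' is not defined"))
      next
    }
    domain_ok <- sdim == spec$domain_dimension
    range_ok <- if (spec$name == "has_contraindication") {
      odim %in% c("Contraindication", "Population")
    } else odim == spec$range_dimension
    if (!domain_ok || !range_ok) {
      v <- add("coherence", "domain_range_violation", ri$instance_id[i],
               paste0(sdim, " -", ri$relation[i], "-> ", odim, " violates the relation signature"))
    }
  }

  bad_iri <- !stringr::str_detect(cls$iri, "^ADR[0-9]{6}$")
  for (i in which(bad_iri)) {
    v <- add("traceability", "iri_scheme_violation", cls$iri[i],
             "class IRI does not match the ADR+6-digit scheme")
  }
  no_cite <- which(is.na(ri$citation) | !nzchar(ri$citation))
  for (i in no_cite) {
    v <- add("traceability", "missing_annotation", ri$instance_id[i],
             "relation instance lacks a source citation")
  }
  un <- graph$units
  for (i in which(is.na(un$citation) | !nzchar(un$citation))) {
    v <- add("traceability", "missing_annotation", un$unit_id[i],
             "knowledge unit lacks a source citation")
  }
  v
}

#' Test two ontology graphs for equality
#'
#' Equality of IRIs, class attributes, relation instances, unit nodes and
#' data properties, after canonical row ordering.
#'
#' @param g1,g2 `adr_ontology_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graphs_equal <- function(g1, g2) {
  norm <- function(g) {
    list(
      metadata = g$metadata["label"],
      classes = canon_df(g$classes, "iri"),
      relation_instances = canon_df(g$relation_instances, "instance_id"),
      units = canon_df(g$units, "unit_id"),
      data_properties = canon_df(g$data_properties, c("concept_id", "property", "value"))
    )
  }
  isTRUE(all.equal(norm(g1), norm(g2), check.attributes = FALSE))
}

canon_df <- function(df, keys) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- df[do.call(order, c(unname(df[keys]), list(method = "radix"))), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @export
print.adr_ontology_graph <- function(x, ...) {
  s <- ontology_stats(x)
  cat("<adr_ontology_graph> '", x$metadata$label, "': ", s$class_count,
      " classes, ", s$relation_count, " relation instances, ",
      s$unit_node_count, " knowledge units\n", sep = "")
  invisible(x)
}
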