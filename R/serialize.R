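# Serialization of ontology graphs: Turtle, OWL/XML (RDF/XML), and the
# package's own lossless JSON dialect — plus the corresponding readers.

#' Serialize an ontology graph
#'
#' Turtle and OWL/XML render classes as `owl:Class` declarations with
#' subclass edges, the eight relation types as `owl:ObjectProperty`
#' declarations, provenance-bearing relation instances and knowledge units
#' as reified resources (so every assertion keeps its source annotation),
#' concept data properties as literals on the class node, and the direct
#' subject-predicate-object triples as a convenience view. JSON is the
#' package's own lossless dialect.
#'
#' @param graph An `adr_ontology_graph`.
#' @param path Output file path.
#' @param format One of `"turtle"`, `"owl_xml"`, `"json"`; default inferred
#'   from the path extension (`.ttl`, `.owl`/`.xml`/`.rdf`, `.json`).
#' @return `path`, invisibly.
#' @export
serialize_ontology <- function(graph, path, format = NULL) {
  stopifnot(inherits(graph, "adr_ontology_graph"))
  format <- format %||% format_from_extension(path)
  switch(format,
    turtle = write_turtle(graph, path),
    owl_xml = write_owl_xml(graph, path),
    json = write_graph_json(graph, path),
    rlang::abort(paste0("unknown format '", format,
                        "'; use turtle, owl_xml or json"))
  )
  invisible(path)
}

#' Load an ontology graph from a serialized file
#'
#' Reads any of the three formats written by [serialize_ontology()] and
#' reconstructs a graph equal (under [graphs_equal()]) to the original.
#'
#' @param path File path.
#' @param format Optional format override.
#' @return An `adr_ontology_graph`.
#' @export
load_ontology <- function(path, format = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  format <- format %||% format_from_extension(path)
  switch(format,
    turtle = read_turtle(path),
    owl_xml = read_owl_xml(path),
    json = read_graph_json(path),
    rlang::abort(paste0("unknown format '", format, "'"))
  )
}

format_from_extension <- function(path) {
  switch(tolower(tools::file_ext(path)),
    ttl = , turtle = "turtle",
    owl = , xml = , rdf = "owl_xml",
    json = "json",
    rlang::abort(paste0("cannot infer format from extension of '", path, "'"))
  )
}

# ---------------------------------------------------------------- JSON ----

write_graph_json <- function(graph, path) {
  obj <- list(
    dialect = "adronto-graph",
    version = 1L,
    metadata = graph$metadata,
    classes = graph$classes,
    relation_instances = graph$relation_instances,
    units = graph$units,
    data_properties = graph$data_properties
  )
  json <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  writeLines(as.character(json), path, useBytes = TRUE)
}

read_graph_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$dialect, "adronto-graph")) {
    rlang::abort(paste0("parse error in ", path, ": not an adronto graph JSON"))
  }
  cols_to_tbl <- function(x, template) {
    out <- template[0, ]
    if (is.null(x) || length(x) == 0) return(out)
    df <- tibble::as_tibble(lapply(names(template), function(nm) {
      col <- x[[nm]]
      if (is.null(col)) col <- rep(NA, length(x[[1]]))
      cast_column(col, template[[nm]])
    }) |> stats::setNames(names(template)))
    df
  }
  structure(
    list(
      metadata = list(label = obj$metadata$label),
      classes = cols_to_tbl(obj$classes, empty_classes()),
      relation_instances = cols_to_tbl(obj$relation_instances, empty_rel_instances()),
      units = cols_to_tbl(obj$units, flatten_units(empty_units())),
      data_properties = cols_to_tbl(obj$data_properties, empty_data_properties())
    ),
    class = "adr_ontology_graph"
  )
}

cast_column <- function(col, template_col) {
  if (is.integer(template_col)) as.integer(col)
  else if (is.numeric(template_col)) as.numeric(col)
  else if (is.logical(template_col)) as.logical(col)
  else as.character(col)
}

empty_classes <- function() {
  tibble::tibble(
    concept_id = character(0), iri = character(0), label = character(0),
    dimension = character(0), level = character(0), parent_id = character(0),
    category = character(0), provisional = logical(0), builtin = logical(0)
  )
}

empty_rel_instances <- function() {
  tibble::tibble(
    instance_id = character(0), subject_id = character(0), relation = character(0),
    object_id = character(0), subject_iri = character(0), object_iri = character(0),
    document_id = character(0), section_index = integer(0),
    start = integer(0), end = integer(0), multiplicity = integer(0),
    citation = character(0)
  )
}

empty_data_properties <- function() {
  tibble::tibble(concept_id = character(0), property = character(0), value = character(0))
}

# -------------------------------------------------------------- Turtle ----

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x
}

ttl_lit <- function(x) paste0("\"", ttl_escape(x), "\"")
ttl_int <- function(x) format(as.integer(x))
ttl_dbl <- function(x) paste0("\"", format(x, digits = 15), "\"^^xsd:double")
ttl_bool <- function(x) ifelse(x, "true", "false")

# Internal: one subject block from (predicate, object-token) pairs.
ttl_block <- function(subject, pairs) {
  body <- paste0("    ", pairs[, 1], " ", pairs[, 2], collapse = " ;\n")
  paste0(subject, "\n", body, " .")
}

write_turtle <- function(graph, path) {
  out <- c(
    paste0("@prefix adr: <", ADR_BASE_IRI, "> ."),
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "",
    ttl_block("adr:ontology", rbind(
      c("a", "owl:Ontology"),
      c("rdfs:label", ttl_lit(graph$metadata$label))
    )),
    "",
    paste0("adr:", adr_relations()$name, " a owl:ObjectProperty ."),
    ""
  )

  cls <- graph$classes
  id2iri <- stats::setNames(cls$iri, cls$concept_id)
  dp <- graph$data_properties
  class_blocks <- vapply(seq_len(nrow(cls)), function(i) {
    pairs <- rbind(
      c("a", "owl:Class"),
      c("rdfs:label", ttl_lit(cls$label[i])),
      c("adr:conceptId", ttl_lit(cls$concept_id[i])),
      c("adr:dimension", ttl_lit(cls$dimension[i])),
      c("adr:level", ttl_lit(cls$level[i])),
      c("adr:provisional", ttl_bool(cls$provisional[i])),
      c("adr:builtin", ttl_bool(cls$builtin[i]))
    )
    if (!is.na(cls$category[i])) {
      pairs <- rbind(pairs, c("adr:category", ttl_lit(cls$category[i])))
    }
    if (!is.na(cls$parent_id[i]) && cls$parent_id[i] %in% names(id2iri)) {
      pairs <- rbind(pairs, c("rdfs:subClassOf", paste0("adr:", id2iri[[cls$parent_id[i]]])))
    }
    d <- dp[dp$concept_id == cls$concept_id[i], ]
    for (k in seq_len(nrow(d))) {
      pairs <- rbind(pairs, c(paste0("adr:dp_", d$property[k]), ttl_lit(d$value[k])))
    }
    ttl_block(paste0("adr:", cls$iri[i]), pairs)
  }, character(1))

  ri <- graph$relation_instances
  rel_blocks <- vapply(seq_len(nrow(ri)), function(i) {
    pairs <- rbind(
      c("a", "adr:RelationAssertion"),
      c("adr:subject", paste0("adr:", ri$subject_iri[i])),
      c("adr:predicate", paste0("adr:", ri$relation[i])),
      c("adr:object", paste0("adr:", ri$object_iri[i])),
      c("adr:subjectConceptId", ttl_lit(ri$subject_id[i])),
      c("adr:objectConceptId", ttl_lit(ri$object_id[i])),
      c("adr:documentId", ttl_lit(ri$document_id[i])),
      c("adr:sectionIndex", ttl_int(ri$section_index[i])),
      c("adr:spanStart", ttl_int(ri$start[i])),
      c("adr:spanEnd", ttl_int(ri$end[i])),
      c("adr:multiplicity", ttl_int(ri$multiplicity[i])),
      c("adr:sourceCitation", ttl_lit(ri$citation[i]))
    )
    ttl_block(paste0("adr:", ri$instance_id[i]), pairs)
  }, character(1))
  direct <- if (nrow(ri)) {
    paste0("adr:", ri$subject_iri, " adr:", ri$relation, " adr:", ri$object_iri, " .")
  } else character(0)

  un <- graph$units
  unit_blocks <- vapply(seq_len(nrow(un)), function(i) {
    pairs <- rbind(
      c("a", "adr:KnowledgeUnit"),
      c("adr:unitKey", ttl_lit(un$unit_id[i])),
      c("adr:drug", paste0("adr:", id2iri[[un$drug_id[i]]])),
      c("adr:has_ADR", paste0("adr:", id2iri[[un$adr_id[i]]])),
      c("adr:occKind", ttl_lit(un$occ_kind[i]))
    )
    if (!is.na(un$occ_value_pct[i])) pairs <- rbind(pairs, c("adr:occValuePct", ttl_dbl(un$occ_value_pct[i])))
    if (!is.na(un$occ_upper_pct[i])) pairs <- rbind(pairs, c("adr:occUpperPct", ttl_dbl(un$occ_upper_pct[i])))
    if (!is.na(un$occ_class[i])) pairs <- rbind(pairs, c("adr:occClass", ttl_lit(un$occ_class[i])))
    if (!is.na(un$severity[i])) pairs <- rbind(pairs, c("adr:has_severity_grade", ttl_int(un$severity[i])))
    if (!is.na(un$mitigation_id[i])) pairs <- rbind(pairs, c("adr:has_mitigation_method", paste0("adr:", id2iri[[un$mitigation_id[i]]])))
    if (!is.na(un$population_id[i])) pairs <- rbind(pairs, c("adr:ADR_occurs_in", paste0("adr:", id2iri[[un$population_id[i]]])))
    pairs <- rbind(pairs,
      c("adr:documentId", ttl_lit(un$document_id[i])),
      c("adr:sectionIndex", ttl_int(un$section_index[i])),
      c("adr:sectionName", ttl_lit(un$section[i])),
      c("adr:sourceCitation", ttl_lit(un$citation[i]))
    )
    ttl_block(paste0("adr:U", sprintf("%07d", i)), pairs)
  }, character(1))

  writeLines(c(out, class_blocks, "", rel_blocks, "", direct, "", unit_blocks),
             path, useBytes = TRUE)
}

# Internal: split a Turtle document into statements, honouring quotes.
ttl_statements <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- character(0)
  buf <- character(0)
  in_str <- FALSE
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_str) {
      buf <- c(buf, ch)
      if (ch == "\\" && i < n) {
        buf <- c(buf, chars[i + 1]); i <- i + 2; next
      }
      if (ch == "\"") in_str <- FALSE
    } else if (ch == "\"") {
      in_str <- TRUE; buf <- c(buf, ch)
    } else if (ch == "." &&
               (i == n || chars[i + 1] %in% c("\n", "\r", " ")) &&
               (i == 1 || chars[i - 1] %in% c(" ", "\n"))) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1
  }
  out <- stringr::str_trim(out)
  out[nzchar(out) & !stringr::str_starts(out, "@prefix")]
}

# Internal: split one statement into subject and (predicate, object) pairs.
ttl_parse_statement <- function(stmt) {
  parts <- strsplit_outside_quotes(stmt, ";")
  first <- stringr::str_trim(parts[1])
  m <- stringr::str_match(first, "^(\\S+)\\s+([\\s\\S]*)$")
  subject <- m[1, 2]
  po <- c(m[1, 3], stringr::str_trim(parts[-1]))
  pairs <- lapply(po, function(p) {
    p <- stringr::str_trim(p)
    mm <- stringr::str_match(p, "^(\\S+)\\s+([\\s\\S]*)$")
    c(mm[1, 2], stringr::str_trim(mm[1, 3]))
  })
  list(subject = subject, pairs = do.call(rbind, pairs))
}

strsplit_outside_quotes <- function(x, sep) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  out <- character(0); buf <- character(0); in_str <- FALSE
  i <- 1; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_str) {
      buf <- c(buf, ch)
      if (ch == "\\" && i < n) { buf <- c(buf, chars[i + 1]); i <- i + 2; next }
      if (ch == "\"") in_str <- FALSE
    } else if (ch == "\"") {
      in_str <- TRUE; buf <- c(buf, ch)
    } else if (ch == sep) {
      out <- c(out, paste(buf, collapse = "")); buf <- character(0)
    } else buf <- c(buf, ch)
    i <- i + 1
  }
  c(out, paste(buf, collapse = ""))
}

ttl_unescape <- function(x) {
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  x <- gsub("\\\\", "\\", x, fixed = TRUE)
  x
}

# Internal: object token -> R value. Resources keep their "adr:IRI" form
# with the prefix stripped.
ttl_object_value <- function(tok) {
  if (stringr::str_starts(tok, "\"")) {
    m <- stringr::str_match(tok, "^\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^\\S+)?$")
    val <- ttl_unescape(m[1, 2])
    if (stringr::str_detect(tok, "\\^\\^xsd:double$")) return(as.numeric(val))
    return(val)
  }
  if (tok %in% c("true", "false")) return(tok == "true")
  if (stringr::str_detect(tok, "^-?[0-9]+$")) return(as.integer(tok))
  stringr::str_remove(tok, "^adr:")
}

read_turtle <- function(path) {
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  stmts <- ttl_statements(text)
  if (length(stmts) == 0) {
    rlang::abort(paste0("parse error in ", path, ": no Turtle statements found"))
  }
  label <- "ADR ontology"
  classes <- list(); rels <- list(); units <- list(); dps <- list()

  for (s in stmts) {
    st <- tryCatch(ttl_parse_statement(s), error = function(e) NULL)
    if (is.null(st) || is.null(st$pairs)) {
      rlang::abort(paste0("parse error in ", path, " near: ",
                          stringr::str_sub(s, 1, 60)))
    }
    preds <- st$pairs[, 1]
    objs <- st$pairs[, 2]
    get <- function(p, default = NA) {
      j <- which(preds == p)
      if (length(j)) ttl_object_value(objs[j[1]]) else default
    }
    type <- get("a", NA_character_)
    subj <- stringr::str_remove(st$subject, "^adr:")

    if (identical(type, "owl:Ontology")) {
      label <- get("rdfs:label", label)
    } else if (identical(type, "owl:Class")) {
      cid <- get("adr:conceptId")
      classes[[length(classes) + 1]] <- tibble::tibble(
        concept_id = cid, iri = subj,
        label = get("rdfs:label"),
        dimension = get("adr:dimension"), level = get("adr:level"),
        parent_iri = get("rdfs:subClassOf", NA_character_),
        category = get("adr:category", NA_character_),
        provisional = get("adr:provisional", FALSE),
        builtin = get("adr:builtin", FALSE)
      )
      for (j in which(stringr::str_starts(preds, "adr:dp_"))) {
        dps[[length(dps) + 1]] <- tibble::tibble(
          concept_id = cid,
          property = stringr::str_remove(preds[j], "^adr:dp_"),
          value = as.character(ttl_object_value(objs[j]))
        )
      }
    } else if (identical(type, "RelationAssertion")) {
      rels[[length(rels) + 1]] <- tibble::tibble(
        instance_id = subj,
        subject_id = get("adr:subjectConceptId"),
        relation = get("adr:predicate"),
        object_id = get("adr:objectConceptId"),
        subject_iri = get("adr:subject"), object_iri = get("adr:object"),
        document_id = get("adr:documentId"),
        section_index = as.integer(get("adr:sectionIndex")),
        start = as.integer(get("adr:spanStart")),
        end = as.integer(get("adr:spanEnd")),
        multiplicity = as.integer(get("adr:multiplicity")),
        citation = get("adr:sourceCitation")
      )
    } else if (identical(type, "KnowledgeUnit")) {
      units[[length(units) + 1]] <- tibble::tibble(
        unit_id = get("adr:unitKey"),
        drug_iri = get("adr:drug"), adr_iri = get("adr:has_ADR"),
        occ_kind = get("adr:occKind"),
        occ_value_pct = as.numeric(get("adr:occValuePct", NA_real_)),
        occ_upper_pct = as.numeric(get("adr:occUpperPct", NA_real_)),
        occ_class = get("adr:occClass", NA_character_),
        severity = as.integer(get("adr:has_severity_grade", NA_integer_)),
        mitigation_iri = get("adr:has_mitigation_method", NA_character_),
        population_iri = get("adr:ADR_occurs_in", NA_character_),
        document_id = get("adr:documentId"),
        section_index = as.integer(get("adr:sectionIndex")),
        section = get("adr:sectionName"),
        citation = get("adr:sourceCitation")
      )
    }
    # direct convenience triples (no rdf:type) are a derived view: skipped
  }
  assemble_graph(label, classes, rels, units, dps)
}

# Internal: shared reconstruction for turtle/xml readers (iri-linked
# parents/units back to concept ids).
assemble_graph <- function(label, classes, rels, units, dps) {
  cls <- if (length(classes)) dplyr::bind_rows(classes) else {
    dplyr::mutate(empty_classes(), parent_iri = character(0), .keep = "all")
  }
  iri2id <- stats::setNames(cls$concept_id, cls$iri)
  cls$parent_id <- ifelse(is.na(cls$parent_iri), NA_character_,
                          unname(iri2id[cls$parent_iri]))
  cls <- cls[, names(empty_classes())]
  ri <- if (length(rels)) dplyr::bind_rows(rels) else empty_rel_instances()
  un0 <- if (length(units)) dplyr::bind_rows(units) else NULL
  un <- flatten_units(empty_units())
  if (!is.null(un0)) {
    un <- tibble::tibble(
      unit_id = un0$unit_id,
      drug_id = unname(iri2id[un0$drug_iri]),
      adr_id = unname(iri2id[un0$adr_iri]),
      occ_kind = un0$occ_kind,
      occ_value_pct = un0$occ_value_pct, occ_upper_pct = un0$occ_upper_pct,
      occ_class = un0$occ_class, severity = un0$severity,
      mitigation_id = ifelse(is.na(un0$mitigation_iri), NA_character_,
                             unname(iri2id[un0$mitigation_iri])),
      population_id = ifelse(is.na(un0$population_iri), NA_character_,
                             unname(iri2id[un0$population_iri])),
      document_id = un0$document_id, section_index = un0$section_index,
      section = un0$section, citation = un0$citation
    )
    un <- un[order(un$document_id, un$section_index, un$unit_id, method = "radix"), ]
  }
  dp <- if (length(dps)) dplyr::bind_rows(dps) else empty_data_properties()
  dp <- dp[order(dp$concept_id, dp$property, dp$value, method = "radix"), ]
  structure(
    list(
      metadata = list(label = label),
      classes = tibble::as_tibble(cls),
      relation_instances = tibble::as_tibble(ri),
      units = tibble::as_tibble(un),
      data_properties = tibble::as_tibble(dp)
    ),
    class = "adr_ontology_graph"
  )
}

# ------------------------------------------------------------- OWL/XML ----

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"

write_owl_xml <- function(graph, path) {
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = RDF_NS, "xmlns:owl" = OWL_NS,
    "xmlns:rdfs" = RDFS_NS, "xmlns:adr" = ADR_BASE_IRI
  )
  res <- function(x) paste0(ADR_BASE_IRI, x)
  onto <- xml2::xml_add_child(doc, "owl:Ontology", "rdf:about" = res("ontology"))
  xml2::xml_add_child(onto, "rdfs:label", graph$metadata$label)
  for (r in adr_relations()$name) {
    xml2::xml_add_child(doc, "owl:ObjectProperty", "rdf:about" = res(r))
  }

  cls <- graph$classes
  id2iri <- stats::setNames(cls$iri, cls$concept_id)
  dp <- graph$data_properties
  for (i in seq_len(nrow(cls))) {
    node <- xml2::xml_add_child(doc, "owl:Class", "rdf:about" = res(cls$iri[i]))
    xml2::xml_add_child(node, "rdfs:label", cls$label[i])
    xml2::xml_add_child(node, "adr:conceptId", cls$concept_id[i])
    xml2::xml_add_child(node, "adr:dimension", cls$dimension[i])
    xml2::xml_add_child(node, "adr:level", cls$level[i])
    xml2::xml_add_child(node, "adr:provisional", tolower(as.character(cls$provisional[i])))
    xml2::xml_add_child(node, "adr:builtin", tolower(as.character(cls$builtin[i])))
    if (!is.na(cls$category[i])) xml2::xml_add_child(node, "adr:category", cls$category[i])
    if (!is.na(cls$parent_id[i]) && cls$parent_id[i] %in% names(id2iri)) {
      xml2::xml_add_child(node, "rdfs:subClassOf",
                          "rdf:resource" = res(id2iri[[cls$parent_id[i]]]))
    }
    d <- dp[dp$concept_id == cls$concept_id[i], ]
    for (k in seq_len(nrow(d))) {
      xml2::xml_add_child(node, paste0("adr:dp_", d$property[k]), d$value[k])
    }
  }

  ri <- graph$relation_instances
  for (i in seq_len(nrow(ri))) {
    node <- xml2::xml_add_child(doc, "adr:RelationAssertion",
                                "rdf:about" = res(ri$instance_id[i]))
    xml2::xml_add_child(node, "adr:subject", "rdf:resource" = res(ri$subject_iri[i]))
    xml2::xml_add_child(node, "adr:predicate", "rdf:resource" = res(ri$relation[i]))
    xml2::xml_add_child(node, "adr:object", "rdf:resource" = res(ri$object_iri[i]))
    xml2::xml_add_child(node, "adr:subjectConceptId", ri$subject_id[i])
    xml2::xml_add_child(node, "adr:objectConceptId", ri$object_id[i])
    xml2::xml_add_child(node, "adr:documentId", ri$document_id[i])
    xml2::xml_add_child(node, "adr:sectionIndex", as.character(ri$section_index[i]))
    xml2::xml_add_child(node, "adr:spanStart", as.character(ri$start[i]))
    xml2::xml_add_child(node, "adr:spanEnd", as.character(ri$end[i]))
    xml2::xml_add_child(node, "adr:multiplicity", as.character(ri$multiplicity[i]))
    xml2::xml_add_child(node, "adr:sourceCitation", ri$citation[i])
  }

  un <- graph$units
  for (i in seq_len(nrow(un))) {
    node <- xml2::xml_add_child(doc, "adr:KnowledgeUnit",
                                "rdf:about" = res(sprintf("U%07d", i)))
    xml2::xml_add_child(node, "adr:unitKey", un$unit_id[i])
    xml2::xml_add_child(node, "adr:drug", "rdf:resource" = res(id2iri[[un$drug_id[i]]]))
    xml2::xml_add_child(node, "adr:has_ADR", "rdf:resource" = res(id2iri[[un$adr_id[i]]]))
    xml2::xml_add_child(node, "adr:occKind", un$occ_kind[i])
    if (!is.na(un$occ_value_pct[i])) {
      xml2::xml_add_child(node, "adr:occValuePct", format(un$occ_value_pct[i], digits = 15))
    }
    if (!is.na(un$occ_upper_pct[i])) {
      xml2::xml_add_child(node, "adr:occUpperPct", format(un$occ_upper_pct[i], digits = 15))
    }
    if (!is.na(un$occ_class[i])) xml2::xml_add_child(node, "adr:occClass", un$occ_class[i])
    if (!is.na(un$severity[i])) {
      xml2::xml_add_child(node, "adr:has_severity_grade", as.character(un$severity[i]))
    }
    if (!is.na(un$mitigation_id[i])) {
      xml2::xml_add_child(node, "adr:has_mitigation_method",
                          "rdf:resource" = res(id2iri[[un$mitigation_id[i]]]))
    }
    if (!is.na(un$population_id[i])) {
      xml2::xml_add_child(node, "adr:ADR_occurs_in",
                          "rdf:resource" = res(id2iri[[un$population_id[i]]]))
    }
    xml2::xml_add_child(node, "adr:documentId", un$document_id[i])
    xml2::xml_add_child(node, "adr:sectionIndex", as.character(un$section_index[i]))
    xml2::xml_add_child(node, "adr:sectionName", un$section[i])
    xml2::xml_add_child(node, "adr:sourceCitation", un$citation[i])
  }
  xml2::write_xml(doc, path)
}

read_owl_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    rlang::abort(paste0("parse error in ", path, ": ", conditionMessage(e)))
  })
  kids <- xml2::xml_children(doc)
  strip_iri <- function(x) stringr::str_remove(x, stringr::fixed(ADR_BASE_IRI))
  label <- "ADR ontology"
  classes <- list(); rels <- list(); units <- list(); dps <- list()

  for (node in kids) {
    nm <- xml2::xml_name(node)
    fields <- xml2::xml_children(node)
    fnames <- xml2::xml_name(fields)
    txt <- function(f, default = NA_character_) {
      j <- which(fnames == f)
      if (length(j)) xml2::xml_text(fields[[j[1]]]) else default
    }
    resf <- function(f, default = NA_character_) {
      j <- which(fnames == f)
      if (length(j)) strip_iri(xml2::xml_attr(fields[[j[1]]], "resource")) else default
    }
    about <- strip_iri(xml2::xml_attr(node, "about"))

    if (nm == "Ontology") {
      label <- txt("label", label)
    } else if (nm == "Class") {
      cid <- txt("conceptId")
      classes[[length(classes) + 1]] <- tibble::tibble(
        concept_id = cid, iri = about, label = txt("label"),
        dimension = txt("dimension"), level = txt("level"),
        parent_iri = resf("subClassOf"),
        category = txt("category"),
        provisional = identical(txt("provisional"), "true"),
        builtin = identical(txt("builtin"), "true")
      )
      for (j in which(stringr::str_starts(fnames, "dp_"))) {
        dps[[length(dps) + 1]] <- tibble::tibble(
          concept_id = cid,
          property = stringr::str_remove(fnames[j], "^dp_"),
          value = xml2::xml_text(fields[[j]])
        )
      }
    } else if (nm == "RelationAssertion") {
      rels[[length(rels) + 1]] <- tibble::tibble(
        instance_id = about,
        subject_id = txt("subjectConceptId"), relation = resf("predicate"),
        object_id = txt("objectConceptId"),
        subject_iri = resf("subject"), object_iri = resf("object"),
        document_id = txt("documentId"),
        section_index = as.integer(txt("sectionIndex")),
        start = as.integer(txt("spanStart")), end = as.integer(txt("spanEnd")),
        multiplicity = as.integer(txt("multiplicity")),
        citation = txt("sourceCitation")
      )
    } else if (nm == "KnowledgeUnit") {
      units[[length(units) + 1]] <- tibble::tibble(
        unit_id = txt("unitKey"),
        drug_iri = resf("drug"), adr_iri = resf("has_ADR"),
        occ_kind = txt("occKind"),
        occ_value_pct = as.numeric(txt("occValuePct", NA_character_)),
        occ_upper_pct = as.numeric(txt("occUpperPct", NA_character_)),
        occ_class = txt("occClass"),
        severity = as.integer(txt("has_severity_grade", NA_character_)),
        mitigation_iri = resf("has_mitigation_method"),
        population_iri = resf("ADR_occurs_in"),
        document_id = txt("documentId"),
        section_index = as.integer(txt("sectionIndex")),
        section = txt("sectionName"),
        citation = txt("sourceCitation")
      )
    }
  }
  assemble_graph(label, classes, rels, units, dps)
}
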