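# Bioinformatic summaries over an ontology graph: triple-type distribution,
# per-ingredient tables, category tables, top-ranked ADRs and contraindicated
# populations, frequency/severity distributions.

#' Shared percentage operation
#'
#' Every percentage in every report derives from this one operation:
#' `100 * numerator / denominator`, rounded half-away-from-zero to 1 or 2
#' decimal places (the two precisions used in the printed tables and the
#' running text, respectively).
#'
#' @param numerator,denominator Counts (denominator > 0). Vectorised over the
#'   numerator.
#' @param decimals 1 or 2.
#' @return Numeric percentage(s).
#' @export
#' @examples
#' percentage(7725, 15711, 2)  # 49.17
#' percentage(141, 165, 1)     # 85.5
percentage <- function(numerator, denominator, decimals = 2) {
  if (length(denominator) != 1 || is.na(denominator) || denominator <= 0) {
    rlang::abort("`denominator` must be a single positive count")
  }
  if (!decimals %in% c(1, 2)) rlang::abort("`decimals` must be 1 or 2")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Internal: lookups into the graph's class table.
class_lookup <- function(graph) {
  stats::setNames(seq_len(nrow(graph$classes)), graph$classes$concept_id)
}

class_field <- function(graph, ids, field) {
  graph$classes[[field]][match(ids, graph$classes$concept_id)]
}

# Internal: category of an ADR concept inside a graph (own category, else the
# nearest categorised ancestor's).
graph_category <- function(graph, ids) {
  cls <- graph$classes
  parent <- stats::setNames(cls$parent_id, cls$concept_id)
  cat <- stats::setNames(cls$category, cls$concept_id)
  vapply(ids, function(id) {
    cur <- id
    while (!is.na(cur)) {
      if (!is.na(cat[[cur]])) return(cat[[cur]])
      cur <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Internal: descending count, ties broken by case-folded label (radix order
# for locale independence).
rank_rows <- function(df, count_col, label_col) {
  df[order(-df[[count_col]], normalize_surface(df[[label_col]]), method = "radix"), ]
}

#' Distribution of relation instances by type
#'
#' Count and percentage of the total relation count for each of the eight
#' relation types (context relations counted at the merged drug-ADR pair
#' level, as in [ontology_stats()]). Percentages at 2 decimals.
#'
#' @param graph An `adr_ontology_graph`.
#' @return Tibble with `relation`, `count`, `pct`.
#' @export
triple_type_distribution <- function(graph) {
  s <- ontology_stats(graph)
  counts <- s$relation_count_by_type
  tibble::tibble(
    relation = names(counts),
    count = as.integer(counts),
    pct = if (s$relation_count > 0) {
      percentage(as.integer(counts), s$relation_count, 2)
    } else rep(NA_real_, length(counts))
  )
}

# Internal: has_ADR pair table (drug_id, adr_id) from deduped relation
# instances.
adr_pairs <- function(graph) {
  ri <- graph$relation_instances
  ri[ri$relation == "has_ADR", c("subject_id", "object_id")]
}

#' Per-ingredient summary of drugs and their ADRs
#'
#' For each active ingredient: number of drug products (and share of retained
#' drugs), number of drug-ADR pairs (share of retained pairs), number of
#' unique ADRs at PT level (share of retained unique ADRs), the major ADRs
#' (top `n_major` by number of drugs reporting them within the ingredient),
#' and the dosage forms and administration routes on record. Shares use 2
#' decimals. Exclusions (e.g. topically administered products) remove drugs
#' before any denominator is computed.
#'
#' @param graph An `adr_ontology_graph`.
#' @param ingredient_map Optional named character vector drug concept_id ->
#'   ingredient; defaults to the `ingredient` data property. Drugs without an
#'   ingredient are bucketed under `"unassigned"` with a warning.
#' @param exclusions Either a character vector of drug concept ids to drop,
#'   or `list(routes_not_in = c("oral", "intravenous"))` to drop every drug
#'   with an administration route outside the allowed set.
#' @param n_major Number of major ADRs listed per ingredient (default 4).
#' @return Tibble with one row per ingredient.
#' @export
per_ingredient_summary <- function(graph, ingredient_map = NULL,
                                   exclusions = NULL, n_major = 4) {
  drugs <- graph$classes$concept_id[graph$classes$dimension == "Drug"]
  if (is.null(ingredient_map)) {
    dp <- graph$data_properties
    ing <- dp[dp$property == "ingredient", ]
    ingredient_map <- stats::setNames(ing$value, ing$concept_id)
  }

  if (!is.null(exclusions)) {
    if (is.list(exclusions) && !is.null(exclusions$routes_not_in)) {
      allowed <- normalize_surface(exclusions$routes_not_in)
      ri <- graph$relation_instances
      routes <- ri[ri$relation == "has_administration_route", ]
      routes$route <- normalize_surface(class_field(graph, routes$object_id, "label"))
      bad <- unique(routes$subject_id[!routes$route %in% allowed])
      drugs <- setdiff(drugs, bad)
    } else {
      drugs <- setdiff(drugs, unlist(exclusions))
    }
  }

  pairs <- adr_pairs(graph)
  pairs <- pairs[pairs$subject_id %in% drugs, ]
  total_drugs <- length(drugs)
  total_pairs <- nrow(pairs)
  total_adrs <- length(unique(pairs$object_id))

  ing_of <- function(ids) {
    out <- unname(ingredient_map[ids])
    if (any(is.na(out))) {
      rlang::warn(paste0(
        sum(is.na(out)), " drug(s) lack an ingredient annotation; bucketed as 'unassigned'"
      ))
      out[is.na(out)] <- "unassigned"
    }
    out
  }
  drug_tbl <- tibble::tibble(drug_id = drugs, ingredient = ing_of(drugs))
  pairs$ingredient <- drug_tbl$ingredient[match(pairs$subject_id, drug_tbl$drug_id)]

  ri <- graph$relation_instances
  forms <- ri[ri$relation == "has_dose_form" & ri$subject_id %in% drugs, ]
  routes <- ri[ri$relation == "has_administration_route" & ri$subject_id %in% drugs, ]
  forms$ingredient <- drug_tbl$ingredient[match(forms$subject_id, drug_tbl$drug_id)]
  routes$ingredient <- drug_tbl$ingredient[match(routes$subject_id, drug_tbl$drug_id)]

  rows <- lapply(sort(unique(drug_tbl$ingredient), method = "radix"), function(ing) {
    dd <- drug_tbl$drug_id[drug_tbl$ingredient == ing]
    pp <- pairs[pairs$ingredient == ing, ]
    uniq <- unique(pp$object_id)
    major <- dplyr::count(pp, .data$object_id, name = "n_drugs")
    major$label <- class_field(graph, major$object_id, "label")
    major <- rank_rows(major, "n_drugs", "label")
    tibble::tibble(
      ingredient = ing,
      n_drugs = length(dd),
      drug_pct = percentage(length(dd), total_drugs, 2),
      n_pairs = nrow(pp),
      pair_pct = if (total_pairs > 0) percentage(nrow(pp), total_pairs, 2) else NA_real_,
      n_unique_adrs = length(uniq),
      adr_pct = if (total_adrs > 0) percentage(length(uniq), total_adrs, 2) else NA_real_,
      major_adrs = paste(utils::head(major$label, n_major), collapse = ", "),
      dosage_forms = paste(sort(unique(class_field(
        graph, forms$object_id[forms$ingredient == ing], "label"
      )), method = "radix"), collapse = ", "),
      routes = paste(sort(unique(class_field(
        graph, routes$object_id[routes$ingredient == ing], "label"
      )), method = "radix"), collapse = ", ")
    )
  })
  dplyr::bind_rows(rows)
}

#' Category summary of adverse reactions
#'
#' For each of the 18 ADR categories: the number of drugs with at least one
#' ADR in that category (a drug with five skin reactions counts once for the
#' skin category), the percentage of all drugs (1 decimal), and example ADR
#' labels. ADRs whose category cannot be resolved are counted under
#' `"uncategorized"` with a warning.
#'
#' @param graph An `adr_ontology_graph`.
#' @param n_examples Example labels listed per category (default 5).
#' @return Tibble with `category`, `n_drugs`, `pct`, `example_adrs`, sorted
#'   descending by count.
#' @export
category_summary <- function(graph, n_examples = 5) {
  pairs <- adr_pairs(graph)
  total_drugs <- sum(graph$classes$dimension == "Drug")
  if (nrow(pairs) == 0 || total_drugs == 0) {
    return(tibble::tibble(category = character(0), n_drugs = integer(0),
                          pct = numeric(0), example_adrs = character(0)))
  }
  pairs$category <- graph_category(graph, pairs$object_id)
  if (any(is.na(pairs$category))) {
    rlang::warn(paste0(sum(is.na(pairs$category)),
                       " drug-ADR pair(s) have no resolvable category"))
    pairs$category[is.na(pairs$category)] <- "uncategorized"
  }
  pairs$label <- class_field(graph, pairs$object_id, "label")
  out <- pairs %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(
      n_drugs = dplyr::n_distinct(.data$subject_id),
      example_adrs = paste(utils::head(
        sort(unique(.data$label), method = "radix"), n_examples
      ), collapse = ", "),
      .groups = "drop"
    )
  out$pct <- percentage(out$n_drugs, total_drugs, 1)
  out <- rank_rows(out, "n_drugs", "category")
  out[, c("category", "n_drugs", "pct", "example_adrs")]
}

#' Top-ranked adverse reactions
#'
#' ADRs ranked by the number of distinct drugs asserting them, with the
#' percentage of all drugs (1 decimal) and the ADR's category. Ties are
#' broken alphabetically (case-folded label).
#'
#' @param graph An `adr_ontology_graph`.
#' @param n Number of rows (default 10); more distinct ADRs than `n` are cut,
#'   fewer are all returned.
#' @return Tibble with `adr`, `n_drugs`, `pct`, `category`.
#' @export
top_adrs <- function(graph, n = 10) {
  stopifnot(n >= 1)
  pairs <- adr_pairs(graph)
  total_drugs <- sum(graph$classes$dimension == "Drug")
  if (nrow(pairs) == 0) {
    return(tibble::tibble(adr = character(0), n_drugs = integer(0),
                          pct = numeric(0), category = character(0)))
  }
  out <- dplyr::count(dplyr::distinct(pairs), .data$object_id, name = "n_drugs")
  out$adr <- class_field(graph, out$object_id, "label")
  out$pct <- percentage(out$n_drugs, total_drugs, 1)
  out$category <- graph_category(graph, out$object_id)
  out <- rank_rows(out, "n_drugs", "adr")
  utils::head(out[, c("adr", "n_drugs", "pct", "category")], n)
}

#' Frequency and severity distribution of drug-ADR pairs
#'
#' Buckets the merged drug-ADR pairs by CIOMS frequency class (pairs with an
#' explicit occurrence) and CTCAE grade (pairs with an explicit severity),
#' and reports the explicit counts, their shares of all pairs (2 decimals),
#' and the share of explicit-frequency pairs below the Very Common class
#' (incidence < 10%) — both of the explicit pairs and of all pairs.
#'
#' @param graph An `adr_ontology_graph`.
#' @return List with `n_pairs`, `n_explicit_frequency`,
#'   `explicit_frequency_pct`, `n_explicit_severity`,
#'   `explicit_severity_pct`, `frequency_buckets` (tibble),
#'   `severity_buckets` (tibble), `below_verycommon_n`,
#'   `below_verycommon_pct_of_explicit`, `below_verycommon_pct_of_pairs`.
#' @export
freq_sev_distribution <- function(graph) {
  pu <- pair_units(graph)
  n_pairs <- nrow(pu)
  explicit_f <- pu[pu$occ_kind != "absent", ]
  explicit_s <- pu[!is.na(pu$severity), ]
  fb <- table(factor(explicit_f$occ_class, levels = frequency_class_levels()))
  sb <- table(factor(explicit_s$severity, levels = 1:5))
  below <- sum(as.integer(fb[frequency_class_levels() != "VeryCommon"]))
  list(
    n_pairs = n_pairs,
    n_explicit_frequency = nrow(explicit_f),
    explicit_frequency_pct = if (n_pairs > 0) percentage(nrow(explicit_f), n_pairs, 2) else NA_real_,
    n_explicit_severity = nrow(explicit_s),
    explicit_severity_pct = if (n_pairs > 0) percentage(nrow(explicit_s), n_pairs, 2) else NA_real_,
    frequency_buckets = tibble::tibble(
      class = names(fb), count = as.integer(fb)
    ),
    severity_buckets = tibble::tibble(
      grade = as.integer(names(sb)), count = as.integer(sb)
    ),
    below_verycommon_n = below,
    below_verycommon_pct_of_explicit =
      if (nrow(explicit_f) > 0) percentage(below, nrow(explicit_f), 2) else NA_real_,
    below_verycommon_pct_of_pairs =
      if (n_pairs > 0) percentage(below, n_pairs, 2) else NA_real_
  )
}

#' Top contraindicated populations
#'
#' Population and condition concepts ranked by the number of distinct drugs
#' holding a `has_contraindication` relation to them. Ties alphabetical.
#'
#' @param graph An `adr_ontology_graph`.
#' @param n Number of rows (default 5).
#' @return Tibble with `population`, `n_drugs`, `pct` (of all drugs,
#'   1 decimal); empty when no contraindication relation exists.
#' @export
top_contraindicated_populations <- function(graph, n = 5) {
  stopifnot(n >= 1)
  ri <- graph$relation_instances
  contra <- ri[ri$relation == "has_contraindication", c("subject_id", "object_id")]
  if (nrow(contra) == 0) {
    return(tibble::tibble(population = character(0), n_drugs = integer(0), pct = numeric(0)))
  }
  total_drugs <- sum(graph$classes$dimension == "Drug")
  out <- dplyr::count(dplyr::distinct(contra), .data$object_id, name = "n_drugs")
  out$population <- class_field(graph, out$object_id, "label")
  out$pct <- percentage(out$n_drugs, total_drugs, 1)
  out <- rank_rows(out, "n_drugs", "population")
  utils::head(out[, c("population", "n_drugs", "pct")], n)
}

#' Full summary report
#'
#' Convenience wrapper running every report over a graph.
#'
#' @param graph An `adr_ontology_graph`.
#' @param exclusions Passed to [per_ingredient_summary()].
#' @param n_top Rows for [top_adrs()] (default 10) ; populations use 5.
#' @return List of the individual report objects.
#' @export
summary_report <- function(graph, exclusions = NULL, n_top = 10) {
  list(
    triple_type_distribution = triple_type_distribution(graph),
    ingredient_rows = per_ingredient_summary(graph, exclusions = exclusions),
    category_rows = category_summary(graph),
    top_adrs = top_adrs(graph, n_top),
    freq_sev_distribution = freq_sev_distribution(graph),
    top_populations = top_contraindicated_populations(graph, 5)
  )
}
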