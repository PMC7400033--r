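# Seeded synthetic vocabularies and package-insert corpora with a
# ground-truth manifest, so the whole pipeline is testable without any
# licensed vocabulary or regulator corpus.

# Curated label pools. SOC groups pair a WHOART-style system-organ class
# label with one of the 18 ADR categories and a set of PT labels chosen so
# that no label collides with template wording, hedge words, CIOMS terms or
# severity descriptors.
soc_pool <- function() {
  list(
    list(label = "skin and appendages disorders", category = "Skin reactions",
         pts = c("itching", "skin rash", "photosensitive reaction",
                 "erythema multiforme", "increased sweating", "urticaria")),
    list(label = "central and peripheral nervous system disorders",
         category = "Nervous system reactions",
         pts = c("headache", "dizziness", "convulsion", "tremor",
                 "paresthesia", "vertigo")),
    list(label = "gastro-intestinal system disorders",
         category = "Gastrointestinal reactions",
         pts = c("nausea", "vomiting", "abdominal pain", "diarrhea",
                 "constipation", "stomatitis")),
    list(label = "psychiatric disorders", category = "Mental disorders",
         pts = c("insomnia", "hallucinations", "depression", "agitation",
                 "anxiety", "nervousness")),
    list(label = "body as a whole - general disorders",
         category = "Generalized reactions",
         pts = c("fever", "fatigue", "syncope", "chest pain", "shivering",
                 "edema")),
    list(label = "urinary system disorders", category = "Urinary diseases",
         pts = c("hematuria", "dysuria", "crystalluria",
                 "urinary incontinence", "interstitial nephritis",
                 "renal colic")),
    list(label = "musculo-skeletal system disorders",
         category = "Musculoskeletal diseases",
         pts = c("arthralgia", "myalgia", "muscle weakness", "bone pain",
                 "arthritis", "tendinitis")),
    list(label = "cardiovascular disorders", category = "Cardiovascular diseases",
         pts = c("hypotension", "palpitation", "bradycardia",
                 "ventricular tachycardia", "vasodilatation", "phlebitis"))
  )
}

aux_pools <- function() {
  list(
    Population = c("pregnant women", "teenagers", "infants",
                   "elderly patients", "lactating women", "children"),
    MitigationMethod = c("discontinue the drug", "reduce the dose",
                         "symptomatic treatment", "withdraw treatment"),
    Contraindication = c("quinolone allergy", "central nervous system disease",
                         "epilepsy", "renal impairment", "myasthenia gravis",
                         "hepatic impairment"),
    DosageForm = c("tablet", "capsule", "injectable", "granules"),
    AdministrationRoute = c("oral", "intravenous", "topical")
  )
}

ingredient_pool <- function() {
  c("levofloxacin", "ciprofloxacin", "ofloxacin", "norfloxacin",
    "moxifloxacin", "gatifloxacin", "enoxacin", "pefloxacin",
    "sparfloxacin", "lomefloxacin")
}

# Internal: run code under a seed without disturbing the caller's RNG state.
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic vocabulary fixture
#'
#' Builds a well-formed controlled vocabulary: `n_soc` system-organ classes
#' (each carrying one of the 18 ADR categories), `n_pt_per_soc` preferred
#' terms under each, `n_it_per_pt` included terms under each PT, `n_drugs`
#' drug concepts annotated with an active ingredient, and `n_aux` auxiliary
#' concepts distributed round-robin over the Population, MitigationMethod,
#' Contraindication, DosageForm and AdministrationRoute dimensions. The
#' total concept count is therefore
#' `n_soc * (1 + n_pt_per_soc * (1 + n_it_per_pt)) + n_drugs + n_aux`.
#' Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param n_soc,n_pt_per_soc,n_it_per_pt,n_drugs,n_aux Sizes (>= 1, except
#'   `n_it_per_pt` and `n_aux` which may be 0).
#' @return List: `table` (vocabulary tibble accepted by
#'   [load_vocabulary()]), `manifest` (fixture ground truth: per-dimension
#'   counts and the drug roster with ingredient, dosage-form and route
#'   assignments).
#' @export
make_vocabulary_fixture <- function(seed = 1, n_soc = 3, n_pt_per_soc = 4,
                                    n_it_per_pt = 1, n_drugs = 5, n_aux = 6) {
  stopifnot(n_soc >= 1, n_pt_per_soc >= 1, n_it_per_pt >= 0,
            n_drugs >= 1, n_aux >= 0)
  with_rng_seed(seed, {
    socs <- soc_pool()
    cats <- adr_categories()
    rows <- list()
    it_suffixes <- c("nos", "aggravated", "recurrent")

    for (s in seq_len(n_soc)) {
      if (s <= length(socs)) {
        soc_label <- socs[[s]]$label
        soc_cat <- socs[[s]]$category
        pts <- socs[[s]]$pts
      } else {
        soc_label <- paste0("organ system disorders ", s)
        soc_cat <- cats[((s - 1) %% length(cats)) + 1]
        pts <- character(0)
      }
      soc_id <- sprintf("SOC%03d", s)
      rows[[length(rows) + 1]] <- tibble::tibble(
        concept_id = soc_id, preferred_label = soc_label, synonyms = "",
        dimension = "AdverseDrugReaction", level = "SOC", parent_id = "",
        codes = sprintf("SOC_code=%04d", s), category = soc_cat
      )
      for (p in seq_len(n_pt_per_soc)) {
        pt_label <- if (p <= length(pts)) pts[p] else sprintf("reaction %d-%d", s, p)
        pt_id <- sprintf("PT%03d%02d", s, p)
        rows[[length(rows) + 1]] <- tibble::tibble(
          concept_id = pt_id, preferred_label = pt_label, synonyms = "",
          dimension = "AdverseDrugReaction", level = "PT", parent_id = soc_id,
          codes = sprintf("ARecNO=%03d%02d", s, p), category = ""
        )
        for (k in seq_len(n_it_per_pt)) {
          it_label <- if (k <= length(it_suffixes)) {
            paste(pt_label, it_suffixes[k])
          } else sprintf("%s variant %d", pt_label, k)
          rows[[length(rows) + 1]] <- tibble::tibble(
            concept_id = sprintf("IT%03d%02d%d", s, p, k),
            preferred_label = it_label, synonyms = "",
            dimension = "AdverseDrugReaction", level = "IT", parent_id = pt_id,
            codes = "", category = ""
          )
        }
      }
    }

    # auxiliary concepts, round-robin over the five auxiliary dimensions
    aux <- aux_pools()
    aux_dims <- names(aux)
    aux_taken <- stats::setNames(integer(length(aux_dims)), aux_dims)
    aux_ids <- stats::setNames(vector("list", length(aux_dims)), aux_dims)
    for (a in seq_len(n_aux)) {
      dim <- aux_dims[((a - 1) %% length(aux_dims)) + 1]
      aux_taken[[dim]] <- aux_taken[[dim]] + 1L
      k <- aux_taken[[dim]]
      pool <- aux[[dim]]
      label <- if (k <= length(pool)) pool[k] else {
        paste(tolower(gsub("([a-z])([A-Z])", "\\1 \\2", dim)), "item", k)
      }
      id <- sprintf("AUX%03d", a)
      aux_ids[[dim]] <- c(aux_ids[[dim]], id)
      rows[[length(rows) + 1]] <- tibble::tibble(
        concept_id = id, preferred_label = label, synonyms = "",
        dimension = dim, level = "NA", parent_id = "", codes = "", category = ""
      )
    }

    # drugs: ingredient cycling through a shuffled pool; each drug gets one
    # or two dosage forms and one route from the fixture's aux concepts
    ingredients <- ingredient_pool()[order(sample.int(length(ingredient_pool())))]
    form_words <- c("tablets", "capsules", "injection", "granules")
    drugs <- list()
    for (d in seq_len(n_drugs)) {
      ing <- ingredients[((d - 1) %% length(ingredients)) + 1]
      fw <- form_words[((d - 1) %/% length(ingredients)) %% length(form_words) + 1]
      label <- if (d <= length(ingredients)) paste(ing, fw) else {
        paste(ing, fw, 1 + (d - 1) %/% (length(ingredients) * length(form_words)))
      }
      id <- sprintf("DRUG%03d", d)
      n_forms <- length(aux_ids$DosageForm)
      n_routes <- length(aux_ids$AdministrationRoute)
      forms <- if (n_forms) aux_ids$DosageForm[sample.int(n_forms, min(n_forms, sample(1:2, 1)))] else character(0)
      route <- if (n_routes) aux_ids$AdministrationRoute[sample.int(n_routes, 1)] else character(0)
      drugs[[d]] <- tibble::tibble(
        drug_id = id, label = label, ingredient = ing,
        form_ids = list(sort(forms)), route_ids = list(route)
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        concept_id = id, preferred_label = label, synonyms = "",
        dimension = "Drug", level = "NA", parent_id = "",
        codes = paste0("ingredient=", ing), category = ""
      )
    }

    table <- dplyr::bind_rows(rows)
    manifest <- list(
      seed = seed,
      n_concepts = nrow(table),
      counts_by_dimension = as.list(table(table$dimension)),
      pt_ids = table$concept_id[table$level == "PT"],
      it_parent = stats::setNames(
        table$parent_id[table$level == "IT"],
        table$concept_id[table$level == "IT"]
      ),
      aux_ids = aux_ids,
      drugs = dplyr::bind_rows(drugs)
    )
    list(table = table, manifest = manifest)
  })
}

#' Corpus generation profile
#'
#' Per-insert distributions of the planted statements. The defaults emulate
#' the shape reported for real quinolone inserts: roughly half of the
#' drug-ADR assertions carry an explicit frequency, just under a tenth carry
#' an explicit severity, and most stated frequencies fall below 10%.
#'
#' @param adrs_per_insert Inclusive range of ADR statements per insert.
#' @param p_numeric,p_term,p_hedge Probabilities that a statement states a
#'   numeric frequency, a CIOMS term, or only a hedge ("may occur"); the
#'   remainder are plain assertions without frequency.
#' @param p_range Probability that a numeric frequency is a range.
#' @param p_low Probability that a numeric frequency lies below 10%.
#' @param p_severity,p_mitigation,p_population Probabilities of explicit
#'   severity, mitigation and population context on a non-hedge statement.
#' @param p_it_surface Probability that the mention uses an included-term
#'   surface form instead of the preferred term.
#' @param p_warnings Probability that an insert has a WARNINGS AND
#'   PRECAUTIONS section; `warnings_adrs` its statement-count range.
#' @param contra_per_insert Range of contraindication objects per insert.
#' @param p_usp Probability of a USE IN SPECIFIC POPULATIONS section.
#' @return A profile list.
#' @export
corpus_profile <- function(adrs_per_insert = c(3, 8),
                           p_numeric = 0.36, p_term = 0.16, p_hedge = 0.20,
                           p_range = 0.10, p_low = 0.90,
                           p_severity = 0.09, p_mitigation = 0.15,
                           p_population = 0.10, p_it_surface = 0.20,
                           p_warnings = 0.50, warnings_adrs = c(1, 2),
                           contra_per_insert = c(1, 3), p_usp = 0.50) {
  as.list(environment())
}

capitalize <- function(x) {
  paste0(toupper(stringr::str_sub(x, 1, 1)), stringr::str_sub(x, 2))
}

cioms_term_text <- function(class) {
  c(VeryRare = "very rare", Rare = "rare", Uncommon = "uncommon",
    Common = "common", VeryCommon = "very common")[[class]]
}

# Internal: compose the sentence for one planted AR statement.
compose_statement <- function(surface, rec) {
  if (rec$hedge) return(paste0(capitalize(surface), " may occur."))
  head <- if (!is.na(rec$severity)) {
    paste(capitalize(c("mild", "moderate", "severe")[rec$severity]), surface)
  } else capitalize(surface)
  freq <- switch(rec$freq_kind,
    point = sprintf(" occurred in %.1f%% of patients", rec$freq_value),
    range = sprintf(" occurred in %.1f%%-%.1f%% of patients",
                    rec$freq_value, rec$freq_upper),
    term = paste0(" was reported as ", cioms_term_text(rec$freq_class)),
    absent = " was observed"
  )
  out <- paste0(head, freq)
  if (!is.na(rec$mitigation_label)) out <- paste0(out, "; ", rec$mitigation_label)
  if (!is.na(rec$population_label)) out <- paste0(out, "; seen in ", rec$population_label)
  paste0(out, ".")
}

#' Generate a synthetic insert corpus with its ground-truth manifest
#'
#' Writes `n_inserts` plain-text package inserts composed from sentence
#' templates over a synthetic vocabulary, one drug per insert, using the five
#' canonical sections. The manifest records every planted fact and the
#' expected post-curation, post-deduplication totals of every analysis
#' report; both corpus and manifest are byte-deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param n_inserts Number of inserts (0 gives an empty corpus).
#' @param profile A [corpus_profile()].
#' @param fixture Optional fixture from [make_vocabulary_fixture()]; by
#'   default one is generated from `seed` with one drug per insert.
#' @param dir Optional directory: inserts are written as
#'   `insert-<k>.txt` plus `vocabulary.tsv` and `manifest.json`.
#' @return List: `texts` (named character vector of insert documents),
#'   `vocab_table`, `vocab` (loaded `adr_vocabulary`), `manifest`.
#' @export
make_corpus <- function(seed = 7, n_inserts = 10, profile = corpus_profile(),
                        fixture = NULL, dir = NULL) {
  if (is.null(fixture)) {
    fixture <- make_vocabulary_fixture(
      seed = seed, n_soc = 5, n_pt_per_soc = 5, n_it_per_pt = 1,
      n_drugs = max(n_inserts, 1), n_aux = 15
    )
  }
  vocab <- load_vocabulary(fixture$table)
  fx <- fixture$manifest
  label_of <- stats::setNames(fixture$table$preferred_label, fixture$table$concept_id)
  it_children <- split(names(fx$it_parent), unname(fx$it_parent))

  inserts <- list()
  texts <- character(0)
  with_rng_seed(seed + 1L, {
    for (j in seq_len(n_inserts)) {
      drug <- fx$drugs[((j - 1) %% nrow(fx$drugs)) + 1, ]
      doc_id <- sprintf("insert-%03d", j)

      n_adr <- sample(profile$adrs_per_insert[1]:profile$adrs_per_insert[2], 1)
      n_adr <- min(n_adr, length(fx$pt_ids))
      adr_ids <- sort(sample(fx$pt_ids, n_adr))

      ar <- purrr::map_dfr(adr_ids, function(pt) {
        u <- stats::runif(1)
        hedge <- FALSE
        freq_kind <- "absent"; fv <- NA_real_; fu <- NA_real_; fc <- NA_character_
        if (u < profile$p_numeric) {
          lo <- if (stats::runif(1) < profile$p_low) sample(1:99, 1) / 10 else sample(100:300, 1) / 10
          if (stats::runif(1) < profile$p_range) {
            hi <- lo + sample(1:50, 1) / 10
            freq_kind <- "range"; fv <- lo; fu <- hi
            fc <- classify_frequency(hi)
          } else {
            freq_kind <- "point"; fv <- lo
            fc <- classify_frequency(lo)
          }
        } else if (u < profile$p_numeric + profile$p_term) {
          freq_kind <- "term"
          fc <- sample(frequency_class_levels(), 1)
        } else if (u < profile$p_numeric + profile$p_term + profile$p_hedge) {
          hedge <- TRUE
        }
        sev <- if (!hedge && stats::runif(1) < profile$p_severity) sample(1:3, 1) else NA_integer_
        mit <- if (!hedge && length(fx$aux_ids$MitigationMethod) &&
                   stats::runif(1) < profile$p_mitigation) {
          sample(fx$aux_ids$MitigationMethod, 1)
        } else NA_character_
        pop <- if (!hedge && length(fx$aux_ids$Population) &&
                   stats::runif(1) < profile$p_population) {
          sample(fx$aux_ids$Population, 1)
        } else NA_character_
        its <- it_children[[pt]]
        use_it <- !is.null(its) && stats::runif(1) < profile$p_it_surface
        tibble::tibble(
          adr_id = pt,
          surface_id = if (use_it) its[1] else pt,
          hedge = hedge, freq_kind = freq_kind,
          freq_value = fv, freq_upper = fu, freq_class = fc,
          severity = sev,
          mitigation_id = mit,
          mitigation_label = if (is.na(mit)) NA_character_ else label_of[[mit]],
          population_id = pop,
          population_label = if (is.na(pop)) NA_character_ else label_of[[pop]]
        )
      })

      warn_ids <- character(0)
      if (stats::runif(1) < profile$p_warnings) {
        nw <- sample(profile$warnings_adrs[1]:profile$warnings_adrs[2], 1)
        warn_ids <- sort(sample(fx$pt_ids, min(nw, length(fx$pt_ids))))
      }

      contra_pool <- c(fx$aux_ids$Population, fx$aux_ids$Contraindication)
      nc <- sample(profile$contra_per_insert[1]:profile$contra_per_insert[2], 1)
      contra_ids <- sort(sample(contra_pool, min(nc, length(contra_pool))))
      usp_ids <- if (length(fx$aux_ids$Population) && stats::runif(1) < profile$p_usp) {
        sample(fx$aux_ids$Population, 1)
      } else character(0)

      ar_sentences <- vapply(seq_len(nrow(ar)), function(k) {
        compose_statement(label_of[[ar$surface_id[k]]], ar[k, ])
      }, character(1))
      warn_sentences <- vapply(warn_ids, function(id) {
        paste0(capitalize(label_of[[id]]), " was observed.")
      }, character(1))
      dose_sentences <- c(
        vapply(drug$form_ids[[1]], function(id) {
          paste0("Supplied as ", label_of[[id]], ".")
        }, character(1)),
        vapply(drug$route_ids[[1]], function(id) {
          paste0("Administered by the ", label_of[[id]], " route.")
        }, character(1))
      )
      contra_sentences <- vapply(contra_ids, function(id) {
        paste0("Contraindicated in ", label_of[[id]], ".")
      }, character(1))
      usp_sentences <- vapply(usp_ids, function(id) {
        paste0("Safety in ", label_of[[id]], " has not been established.")
      }, character(1))

      parts <- c(drug$label, "", "ADVERSE REACTIONS", ar_sentences)
      if (length(warn_sentences)) {
        parts <- c(parts, "", "WARNINGS AND PRECAUTIONS", warn_sentences)
      }
      parts <- c(parts, "", "DOSAGE AND ADMINISTRATION", dose_sentences,
                 "", "CONTRAINDICATIONS", contra_sentences)
      if (length(usp_sentences)) {
        parts <- c(parts, "", "USE IN SPECIFIC POPULATIONS", usp_sentences)
      }
      texts[doc_id] <- paste(parts, collapse = "\n")

      inserts[[j]] <- list(
        document_id = doc_id,
        drug_id = drug$drug_id,
        drug_label = drug$label,
        ingredient = drug$ingredient,
        generation_tag = "synthetic",
        ar = ar,
        warn_ids = warn_ids,
        contra_ids = unique(c(contra_ids, usp_ids)),
        form_ids = drug$form_ids[[1]],
        route_ids = drug$route_ids[[1]]
      )
    }
  })

  manifest <- list(
    seed = seed, n_inserts = n_inserts,
    fixture = fx, inserts = inserts
  )
  manifest$totals <- manifest_totals(manifest)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (doc_id in names(texts)) {
      writeLines(texts[[doc_id]], file.path(dir, paste0(doc_id, ".txt")), useBytes = TRUE)
    }
    write_vocabulary(vocab, file.path(dir, "vocabulary.tsv"))
    jsonlite::write_json(
      manifest["totals"], file.path(dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
  }
  list(texts = texts, vocab_table = fixture$table, vocab = vocab, manifest = manifest)
}

# Internal: recompute the expected totals of every report from the per-insert
# planted facts — arithmetic over ground truth, independent of the
# extraction/analysis code paths it is used to check.
manifest_totals <- function(manifest) {
  fx <- manifest$fixture
  ins <- manifest$inserts

  # per-insert drug-ADR pairs (deduplicated across AR and WARNINGS)
  pair_list <- lapply(ins, function(x) {
    adrs <- unique(c(x$ar$adr_id, x$warn_ids))
    tibble::tibble(drug_id = x$drug_id, adr_id = adrs)
  })
  pairs <- dplyr::bind_rows(c(
    list(tibble::tibble(drug_id = character(0), adr_id = character(0))), pair_list
  ))

  # pair-level context comes from the AR statement of the pair (WARNINGS
  # statements are planted without context)
  ctx <- dplyr::bind_rows(c(list(tibble::tibble(
    drug_id = character(0), adr_id = character(0), freq_kind = character(0),
    freq_class = character(0), severity = integer(0),
    mitigation_id = character(0), population_id = character(0)
  )), lapply(ins, function(x) {
    if (nrow(x$ar) == 0) return(NULL)
    tibble::tibble(
      drug_id = x$drug_id, adr_id = x$ar$adr_id,
      freq_kind = ifelse(x$ar$hedge, "absent", x$ar$freq_kind),
      freq_class = x$ar$freq_class, severity = x$ar$severity,
      mitigation_id = x$ar$mitigation_id, population_id = x$ar$population_id
    )
  })))

  n_pairs <- nrow(pairs)
  counts <- c(
    has_ADR = n_pairs,
    has_occurrence = sum(ctx$freq_kind != "absent"),
    has_severity = sum(!is.na(ctx$severity)),
    ADR_occurs_in = sum(!is.na(ctx$population_id)),
    has_mitigation_method = sum(!is.na(ctx$mitigation_id)),
    has_dose_form = sum(vapply(ins, function(x) length(unique(x$form_ids)), integer(1))),
    has_administration_route = sum(vapply(ins, function(x) length(unique(x$route_ids)), integer(1))),
    has_contraindication = sum(vapply(ins, function(x) length(unique(x$contra_ids)), integer(1)))
  )
  counts <- counts[adr_relations()$name]
  names(counts) <- adr_relations()$name
  relation_count <- sum(counts)

  explicit <- ctx[ctx$freq_kind != "absent", ]
  fb <- table(factor(explicit$freq_class, levels = frequency_class_levels()))
  sb <- table(factor(ctx$severity, levels = 1:5))

  # all fixture drugs are the denominator, mirroring the graph's Drug dimension
  total_drugs <- nrow(fx$drugs)

  list(
    n_inserts = manifest$n_inserts,
    # the ten built-in scale concepts appear once any knowledge unit exists
    class_count = fx$n_concepts + if (n_pairs > 0) 10L else 0L,
    n_pairs = n_pairs,
    n_unique_adrs = length(unique(pairs$adr_id)),
    relation_count = as.integer(relation_count),
    relation_count_by_type = as.list(counts),
    n_explicit_frequency = as.integer(sum(ctx$freq_kind != "absent")),
    n_explicit_severity = as.integer(sum(!is.na(ctx$severity))),
    frequency_buckets = as.list(stats::setNames(as.integer(fb), names(fb))),
    severity_buckets = as.list(stats::setNames(as.integer(sb), paste0("grade", names(sb)))),
    below_verycommon_n = as.integer(sum(fb[names(fb) != "VeryCommon"])),
    n_hedged_statements = sum(vapply(ins, function(x) sum(x$ar$hedge), integer(1))),
    pairs = pairs,
    context = ctx,
    total_drugs = total_drugs
  )
}

#' Expected analysis tables from a corpus manifest
#'
#' Recomputes, from the planted ground truth alone, the tables that
#' [top_adrs()], [top_contraindicated_populations()] and
#' [category_summary()] should produce on the ontology built from the
#' corpus.
#'
#' @param corpus The list returned by [make_corpus()].
#' @return List with `top_adrs`, `top_populations`, `category_rows`.
#' @export
manifest_expected_tables <- function(corpus) {
  manifest <- corpus$manifest
  tab <- corpus$vocab_table
  label_of <- stats::setNames(tab$preferred_label, tab$concept_id)
  parent_of <- stats::setNames(tab$parent_id, tab$concept_id)
  cat_of <- stats::setNames(tab$category, tab$concept_id)
  pt_category <- function(pt) {
    soc <- parent_of[[pt]]
    out <- if (nzchar(cat_of[[pt]])) cat_of[[pt]] else cat_of[[soc]]
    if (!nzchar(out)) NA_character_ else out
  }
  totals <- manifest$totals
  pairs <- totals$pairs
  total_drugs <- totals$total_drugs

  ta <- dplyr::count(pairs, .data$adr_id, name = "n_drugs")
  ta$adr <- unname(label_of[ta$adr_id])
  ta$pct <- percentage(ta$n_drugs, total_drugs, 1)
  ta$category <- vapply(ta$adr_id, pt_category, character(1))
  ta <- rank_rows(ta, "n_drugs", "adr")

  contra <- dplyr::bind_rows(c(
    list(tibble::tibble(drug_id = character(0), object_id = character(0))),
    lapply(manifest$inserts, function(x) {
      if (!length(x$contra_ids)) return(NULL)
      tibble::tibble(drug_id = x$drug_id, object_id = x$contra_ids)
    })
  ))
  tp <- dplyr::count(dplyr::distinct(contra), .data$object_id, name = "n_drugs")
  tp$population <- unname(label_of[tp$object_id])
  tp$pct <- percentage(tp$n_drugs, total_drugs, 1)
  tp <- rank_rows(tp, "n_drugs", "population")

  pc <- pairs
  pc$category <- vapply(pc$adr_id, pt_category, character(1))
  cr <- pc %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(n_drugs = dplyr::n_distinct(.data$drug_id), .groups = "drop")
  cr$pct <- percentage(cr$n_drugs, total_drugs, 1)
  cr <- rank_rows(cr, "n_drugs", "category")

  list(
    top_adrs = ta[, c("adr", "n_drugs", "pct", "category")],
    top_populations = tp[, c("population", "n_drugs", "pct")],
    category_rows = cr[, c("category", "n_drugs", "pct")]
  )
}

#' Run the full pipeline over a corpus
#'
#' Parses every insert, extracts triples and units, applies vagueness
#' filtering, deduplicates, and builds the ontology — the same steps a user
#' would run file by file.
#'
#' @param corpus The list returned by [make_corpus()] (or a compatible list
#'   with `texts` and `vocab`).
#' @param config Extraction settings.
#' @return List with `graph`, `triples` (deduplicated), `units`, `findings`.
#' @export
run_pipeline <- function(corpus, config = extraction_config()) {
  vocab <- corpus$vocab
  all_triples <- empty_triples()
  all_units <- empty_units()
  findings <- list()
  for (doc_id in names(corpus$texts)) {
    insert <- parse_insert(corpus$texts[[doc_id]], doc_id)
    ex <- extract_relations(insert, vocab, config)
    vocab <- ex$vocab
    units <- filter_vague(ex$units)
    findings[[doc_id]] <- validate_units(units, ex$triples, insert, vocab)
    all_triples <- dplyr::bind_rows(all_triples, ex$triples)
    all_units <- dplyr::bind_rows(all_units, units)
  }
  ded <- dedupe(all_triples, vocab)
  graph <- build_ontology(vocab, ded, all_units,
                          metadata = list(label = "synthetic ADR ontology"))
  list(graph = graph, triples = ded, units = all_units,
       findings = dplyr::bind_rows(findings), vocab = vocab)
}
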