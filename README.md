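# adronto

Build and analyse adverse-drug-reaction (ADR) ontologies from drug package
inserts.

## The problem

Package inserts are the official record of a licensed drug's known adverse
reactions, but they are semi-structured prose: titled sections, free-text
frequency statements ("dizziness occurred in 2.3% of patients"), severity
words, mitigation advice and contraindicated populations. Pharmacovigilance
work — safety comparisons across a drug family, decision support, semantic
retrieval — needs that content as formally organised, traceable knowledge
instead.

`adronto` converts a corpus of inserts into an ADR ontology and runs the
standard bioinformatic summaries over it. It is aimed at pharmacovigilance
researchers and biomedical-ontology engineers who have (a) insert texts in a
titled-section dialect and (b) a controlled vocabulary in the WHOART/MedDRA
style (SOC/HLT/PT/IT hierarchy plus synonyms); a seeded synthetic corpus
generator stands in for both when licensed sources cannot be shipped.

## The model

The ontology schema has **nine class dimensions** — adverse drug reaction,
occurrence, severity, population, mitigation method, drug, dosage form,
administration route, contraindication — connected by **eight semantic
relation types** (`has_ADR`, `has_occurrence`, `has_severity`,
`ADR_occurs_in`, `has_mitigation_method`, `has_dose_form`,
`has_administration_route`, `has_contraindication`).

Text becomes knowledge in two steps:

* **NER** — dictionary matching of vocabulary surface forms (preferred
  labels, synonyms, included terms) over section bodies: leftmost-longest,
  non-overlapping, token-boundary-aware; included-term (IT) hits are
  promoted to their preferred term (PT), the canonical reporting unit.
* **RE** — section titles drive the relation: ADVERSE REACTIONS and
  WARNINGS AND PRECAUTIONS yield `has_ADR`, DOSAGE AND ADMINISTRATION
  yields dose forms and routes, CONTRAINDICATIONS and USE IN SPECIFIC
  POPULATIONS yield contraindications.

Each drug-ADR assertion is reified as a **knowledge unit** that bundles the
sentence-scoped context: occurrence — classified on the five CIOMS
frequency classes, Very Rare [0, 0.01%) < Rare [0.01%, 0.1%) <
Uncommon [0.1%, 1%) < Common [1%, 10%) < Very Common [10%, ∞) — severity on
the five CTCAE grades (1 mild … 5 death), mitigation and population.
Machine-executable biocuration rules enforce the two review criteria
(completeness; explicitness — hedged frequency language such as "may occur"
is never recorded as an occurrence), triples are deduplicated into a
nonredundant set with multiplicities, and every class gets an IRI of the
form `ADR` + six digits. Each assertion carries its source citation, so
every statement in the ontology is traceable to a document. Serialisation:
Turtle, OWL/XML, and a lossless JSON dialect.

## Worked example

```r
library(adronto)

corpus <- make_corpus(seed = 7, n_inserts = 10)   # synthetic inserts + ground truth
res    <- run_pipeline(corpus)                    # parse -> NER/RE -> curate -> build
res$graph
#> <adr_ontology_graph> 'synthetic ADR ontology': 90 classes, 156 relation instances, 71 knowledge units

triple_type_distribution(res$graph)
#> # A tibble: 8 × 3
#>   relation                 count   pct
#> 1 has_ADR                     68 43.6
#> 2 has_occurrence              29 18.6
#> 3 has_severity                 6  3.85
#> 4 ADR_occurs_in                1  0.64
#> 5 has_mitigation_method        5  3.21
#> 6 has_dose_form               16 10.3
#> 7 has_administration_route    10  6.41
#> 8 has_contraindication        21 13.5

top_adrs(res$graph, 3)
#>   adr                n_drugs   pct category
#> 1 fever                    5    50 Generalized reactions
#> 2 abdominal pain           4    40 Gastrointestinal reactions
#> 3 increased sweating       4    40 Skin reactions
```

The 90 classes are the 80 synthetic vocabulary concepts plus the ten
occurrence/severity scale classes. Of the 68 deduplicated drug-ADR pairs,
29 (42.65%) carry an explicit frequency and 89.66% of those explicit
frequencies lie below the Very Common class (< 10% incidence) — the shape
the generator's default profile emulates. `top_adrs` counts, for each
preferred term, the number of distinct drugs asserting it and its share of
all drugs. Every number above equals the generator's ground-truth manifest
(`corpus$manifest$totals`); that equality is what the test suite asserts
across 20 seeds.

Serialise and reload:

```r
serialize_ontology(res$graph, "quinolones.ttl")        # or .owl / .json
g2 <- load_ontology("quinolones.ttl")
graphs_equal(res$graph, g2)                            # TRUE
evaluate_ontology(g2)                                  # 0 violations
```

A thin CLI wraps the same functions (`inst/exec/adronto`):

```sh
Rscript inst/exec/adronto synth --seed 7 --n 10 --out-dir corpus
Rscript inst/exec/adronto build --corpus corpus --vocabulary corpus/vocabulary.tsv --out onto.ttl
Rscript inst/exec/adronto stats --ontology onto.ttl --out-dir report
```

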