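---
title: "Methods: from package inserts to an ADR ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from package inserts to an ADR ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adronto)
```

## The model

A package insert describes one drug product. Its adverse-reaction content is
modelled on two axes: ADR information (the reaction itself, its occurrence
frequency, its severity, the affected population, the mitigation method) and
medication instructions (the drug, its dosage forms, administration routes,
and contraindications). These nine class dimensions are closed
(`adr_dimensions()`), as are the eight relation types that connect them
(`adr_relations()`). Four of the relations attach to a drug-ADR *pair*
rather than to the drug — occurrence, severity, mitigation, population — so
the pair is reified as a knowledge unit: a node that carries the `has_ADR`
link plus whichever context links the text explicitly supports. The alias
`has_population` is accepted for `ADR_occurs_in`.

Two fixed scales anchor the context. Occurrence uses the five CIOMS
frequency classes over percentage incidence, half-open on the right:

```{r}
cioms_frequency_classes()
```

The lower bound is inclusive and the upper exclusive, so exactly 0.01% is
Rare and exactly 10% is Very Common. The lowest class is taken as
[0, 0.01): a stated incidence of exactly zero is classified Very Rare
rather than rejected, since inserts occasionally print "0%" for
completeness. Severity uses the five CTCAE grades (`ctcae_grades()`), from
Grade 1 (mild) to Grade 5 (death).

## Assumptions and what "explicit" means

Only explicit statements become context. A numeric percentage, a numeric
range, or one of the five CIOMS terms counts as an explicit frequency; a
CTCAE descriptor word or an explicit "Grade n" token counts as an explicit
severity. Hedged language — "may occur", "occasionally" — is never recorded
as an occurrence: `parse_frequency_expression()` returns an *absent*
observation, and the curation step (`filter_vague()`) additionally clears
context whose provenance sentence matches the configurable hedge list. The
drug-ADR assertion itself always survives curation; only its context is
cleared. Whether the original curators dropped whole triples or only
context for vague statements is unknowable from the outside; keeping the
pair and clearing the context is the conservative choice, because the
assertion "this drug can cause this reaction" is itself explicit in the
text.

Numeric *ranges* ("0.1%–1%") classify by their upper bound. This is the
conservative reading for safety reporting — a range is a claim that the
incidence may be as high as its upper end — and the raw bounds are retained
unmodified on the observation for reporting.

## Text processing choices

**Section detection.** A header is a line that, after stripping an optional
bracketed or numbered marker, matches a canonical title or a configured
alias, case-insensitively. Regulatory dialects differ mainly in these
markers, so the alias table is configuration, not code. Duplicate canonical
sections are retained and processed independently; dropping one would risk
losing triples, and deduplication merges the results downstream anyway.

**Matching is language-neutral.** All matching — section titles, dictionary
NER, frequency and severity terms — goes through one normalizer: Unicode
NFKC, case folding, whitespace collapse, outer punctuation strip. Original
corpora in non-Latin scripts would substitute a word segmenter; here
matching operates directly on normalized character sequences with
word-boundary guards (a term never matches inside a longer alphanumeric
word), which gives the identical observable behaviour on a
space-delimited corpus. The frequency parser uses a lighter variant that
preserves the trailing `%` of numeric expressions.

**NER.** Dictionary matching keeps leftmost-longest non-overlapping
matches. Where two concepts could claim the same span, resolution prefers
the dimension of the querying context, then PT over IT level, then the
lexicographically smallest concept id — determinism is worth more here than
any heuristic cleverness. IT hits are promoted to their PT parent at
resolution time (PT is the canonical reporting level); the raw IT hit is
preserved on the mention for provenance.

**Sentence windows.** Context attaches strictly within the sentence that
contains the ADR mention. Sentences end at `.`, `!`, `?` (and full-width
equivalents); a period between two digits is a decimal point. Semicolons
are deliberately *not* terminators: inserts habitually write the mitigation
after a semicolon ("rash (rare); discontinue the drug"), and cutting the
window there would orphan exactly the context the sentence is stating. If
one sentence holds several ADR mentions and one frequency ("nausea and
vomiting (1–3%)"), the frequency attaches to each of them. Nothing outside
the sentence is ever consulted.

**Negation** is not detected: "no cases of anaphylaxis" would extract
anaphylaxis. The biocuration findings report exists precisely to surface
such cases to a human reviewer; learned NER and negation scope detection
are out of scope.

## Ontology assembly

IRIs follow the `ADR` + six-digit scheme, assigned in ascending
(dimension order, case-folded label) order — a deterministic rule, so
rebuilding from identical inputs is byte-identical. An optional IRI
registry pins existing label-to-IRI assignments across builds; without it,
stability is guaranteed within a build only. The ten scale classes (five
CIOMS, five CTCAE) join the graph only when knowledge units exist to point
at them, so a minimal vocabulary-plus-triples build contains exactly its
own concepts.

Knowledge units are reified nodes rather than OWL class-expression
intersections: reification keeps the graph queryable with plain triple
patterns and serialises losslessly to all three formats (Turtle, OWL/XML,
and the package's JSON dialect). Relation statistics count the four context
relations once per *merged* drug-ADR pair — a pair asserted in both the
adverse-reactions and the warnings section is one `has_ADR` relation, and
its first explicit context in provenance order wins — because that is the
granularity at which per-pair shares ("x% of drug-ADR triples state a
frequency") are meaningful. The raw per-section unit nodes and their link
count are reported separately in `ontology_stats()`.

Relations extracted from USE IN SPECIFIC POPULATIONS are emitted as
`has_contraindication` by default; a configuration switch
(`populations_as_context`) downgrades them to population context for
corpora where that section is informational rather than prohibitive.

The quality evaluation (`evaluate_ontology()`) operationalises the standard
design principles as checks: clarity (label uniqueness within a dimension),
coherence (no subclass cycles, no dangling edges, domain/range conformity),
and traceability (IRI scheme conformance, a non-empty source citation on
every assertion). Serialization is hand-rolled for the package's own
output dialect — the writers emit standard Turtle/RDF-XML constructs
(verified against an independent RDF parser in the test suite), and the
readers guarantee load–serialize round-trips are the identity.

## Analysis conventions

Every percentage in every report derives from one shared operation:
`percentage(numerator, denominator, decimals)`, rounding half-away-from-zero
at 1 decimal (tables) or 2 decimals (running text) — no second rounding
path exists. Two counting conventions coexist and are both implemented
because the published tables switch between them: *pair-level* counting
(drug-ADR triples; the per-ingredient table) and *drug-level* counting
(distinct drugs asserting an ADR or category; the category, top-ADR and
population tables). Ranked lists sort by descending count with
alphabetical (case-folded, byte-order) tie-breaks. "Major ADRs" per
ingredient are the top 4 by within-ingredient multiplicity; the published
tables list 3–4 and state no rule, so the cut-off is a documented,
configurable default. Route-based exclusions (e.g. keeping only oral and
intravenous products) remove drugs *before* any denominator is computed.

## The synthetic corpus

Licensed vocabularies (WHOART, MedDRA, CTCAE) and regulator insert corpora
cannot be redistributed, so `make_vocabulary_fixture()` and `make_corpus()`
generate both, deterministically under a seed. The fixture builds a
SOC/PT/IT hierarchy from curated realistic label pools (ADR preferred
terms, quinolone ingredient names, populations, mitigations, dosage forms,
routes), each SOC carrying one of the 18 ADR categories. Auxiliary
concepts are distributed round-robin over the five auxiliary dimensions so
the concept-count arithmetic stays exact. The corpus composes inserts from
sentence templates — numeric frequencies, ranges, CIOMS terms, severity
adjectives, semicolon-separated mitigation clauses, population phrases,
hedge-only statements — and records every planted fact in a manifest whose
totals are recomputed arithmetically from the per-insert lists,
independently of the extraction code they are used to test.

The default profile mirrors the shape reported for real quinolone inserts:
per insert 3–8 ADR statements, about half with an explicit frequency
(numeric : term ≈ 0.36 : 0.16, a tenth of numerics as ranges), 9% with an
explicit severity (grades 1–3 only, as published inserts report no
life-threatening quinolone ADRs), 90% of stated frequencies below 10%,
modest mitigation (0.15) and population (0.10) context, a 0.20 hedge rate,
and 1–3 contraindications per insert. One drug per insert mirrors the
one-product-one-leaflet structure of the real corpus.

What passing tests on this corpus shows: the pipeline recovers planted
facts exactly when mentions use vocabulary surface forms, and every report
is arithmetically consistent with its inputs. What it does not show:
robustness to misspellings, morphological variation, tables, negation, or
section dialects beyond the alias mechanism — real-corpus performance
depends on vocabulary coverage, which is exactly why the original approach
used licensed terminologies with extensive synonym lists.

## Problem sizes and determinism

The test suite runs the end-to-end recovery on 10-insert corpora across 20
seeds, NER oracle equivalence on 200 random instances (vocabularies up to
50 terms, texts up to 500 characters), and serialization round-trips on 10
corpus-derived graphs in all three formats — sizes chosen so the whole
suite completes in a few minutes while still exercising every code path
several hundred times. All randomness flows from explicit seeds through
one RNG-scoping helper that restores the caller's RNG state, so no test
depends on execution order.

## Known limitations

* Dictionary NER only: recall on real text is bounded by vocabulary
  coverage; no fuzzy matching.
* No negation or speculation scope; hedges are handled lexically.
* The 18-category scheme is modelled as an attribute of SOC-level concepts;
  if a deployment's categories do not align with its SOC classes, the
  mapping must be expressed in the vocabulary file.
* No description-logic reasoning; `evaluate_ontology()` checks structural
  conformance, not logical consistency.
* The Turtle/OWL-XML readers target the package's own output dialect, not
  arbitrary RDF.
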