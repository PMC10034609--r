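---
title: "From hospital source data to OMOP CDM via EN/ISO 13606 and ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hospital source data to OMOP CDM via EN/ISO 13606 and ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehr2omop)
```

## The problem and the approach

Hospitals record care in local schemas with local codes. Research networks
want the same facts in a common analysis model — here the OMOP Common Data
Model (CDM) — without losing the meaning the data had at the bedside.
`ehr2omop` implements a dual-model route between the two worlds:

1. **Archetypes** (EN/ISO 13606 archetype model) formalize each clinical
   concept — diagnosis, episode, administered medication, and so on — as an
   *entry* with typed *elements*, the entry and element being components of
   the standard's reference model (RM). The package ships twelve
   entry-level archetypes.
2. **Normalized extracts**: an archetype-driven ETL reads the source
   tables, binds local codes to ICD-10-CM / LOINC / SNOMED CT, categorizes
   selected concepts (hospital units by level of care), and emits one
   EN/ISO 13606 extract XML per patient and archetype. Extracts keep the
   full granularity of the source and remain *identified*: they are the
   primary-use representation.
3. **A three-layer ontology** represents the knowledge: layer 1 holds one
   class per archetype entry and one property per element (standard-
   agnostic); layer 2 maps each class under `iso13606:Entry` and types each
   property with its RM data-value class; layer 3 annotates classes and
   properties with their OMOP CDM table and column counterparts.
4. **Instance loading** inserts each extract entry into the ontology as a
   typed individual, with RM-typed assertions per element.
5. **Export**: per CDM table, a SPARQL SELECT is generated from layer 3 —
   projecting *every* schema column, mapped or not — executed against the
   instance graph, and post-processed into pseudonymized CSV tables. Ten
   clinical tables are produced: Condition_occurrence, Death,
   Device_exposure, Drug_exposure, Measurement, Observation,
   Observation_period, Person, Visit_detail and Visit_occurrence.

Because the layers are separate named graphs, the design is
standard-agnostic: dropping layer 3 leaves an EN/ISO 13606 ontology;
dropping layers 2–3 leaves a plain concept ontology onto which another
standard could be mapped instead.

## The archetype dialect

Archetypes are authored in a small YAML dialect (entry name, ordered
elements with `node_id`, `kind`, `mandatory`, optional `terminology`)
rather than in ADL: the pipeline needs exactly the entry/element/data-type
structure and the terminology binding, and a closed six-variant set of RM
data values (`CODED_TEXT`, `SIMPLE_TEXT`, `DATE_TIME`, `QUANTITY`,
`IDENTIFIER`, `BOOLEAN`) keeps validation decidable. Only the ENTRY and
ELEMENT levels of the RM are modeled, because all twelve concepts are
entry-level. The diagnosis archetype's six elements (`episode_id`,
`diagnosis`, `diagnosis_datetime`, `patient_id`, `diagnosis_id`, `source`)
are the canonical structure of that concept; the element lists of the other
eleven concepts are reconstructions from their table correspondences and
are flagged as such in the fixture files. The `health_problems` archetype
completes the library but has no extract pipeline: its upstream source is
free text processed outside this toolchain.

```{r}
a <- parse_archetype(ehr2omop_extdata("archetypes", "diagnosis.yaml"))
a
```

## Terminology binding

Mapping tables are plain CSVs (`local_code`, `local_system`,
`target_code`, `target_system`, `display`), one-to-one and case-sensitive.
Binding is total: an unmapped code is preserved as coded text in system
`"local"` and registered in a report, never dropped — the unmapped report
plus the mapped set partitions the input exactly. No external vocabulary
service (e.g. the OHDSI vocabularies) is consulted; exported
`*_concept_id` columns carry `0` ("no matching concept") while
`*_source_value` columns carry the bound codes, which is where this
pipeline deliberately stops short of full OMOP vocabulary normalization.

```{r}
bind_code("D003", "HIS-DIAG", concept_map())
```

## Design choices in the open

Several points were genuinely open and were fixed as follows:

* **Mapping axiom species.** Layer 3 uses annotation-style properties
  (`omop:mapsToTable`, `omop:mapsToColumn`) read by the query generator,
  not `owl:equivalentClass`: the transformation is driven by lookup, not
  by reasoning, and no reasoner is required at build time.
* **Drug provenance.** Administered medication, cumulative drug dose and
  prescribed medication all map to `Drug_exposure`; rows are
  discriminated by `drug_type_concept_id` (32818 EHR administration
  record, 32838 EHR prescription, 32880 standard algorithm for the
  derived cumulative-dose rows) — the one place a concept-id column is
  not `0`, since the CDM distinguishes exposure provenance by type.
* **Tables without archetypes.** `Observation_period` is derived per
  person as the span from earliest admission to latest discharge;
  `Death` from episodes whose discharge disposition is the death code
  (at most one row per person, the latest qualifying episode);
  `Device_exposure` from procedure entries whose bound code is in the
  configured device-code list. These derivation rules are package
  decisions, configured in `omop_mapping.yaml`.
* **Procedure_occurrence.** The default export emits exactly the ten
  clinical tables above; `Procedure_occurrence` (to which the procedure
  archetype maps) can be enabled with
  `derived$procedure_occurrence_enabled`. Non-device procedure instances
  that are consequently not exported are counted as logged exclusions so
  that per-archetype conservation — instances = exported rows + logged
  exclusions — stays exact.
* **Pseudonymization vs source values.** Extracts are identified (primary
  use); exported tables are pseudonymized (secondary use). Identifier
  columns carry HMAC-SHA-256-based 48-bit pseudonyms rendered as
  integers, scoped by identifier namespace (`patient:`, `episode:`, or
  the concept name for row keys) so that the same real-world identifier
  pseudonymizes consistently across tables within a run. The
  anonymization contract overrides OMOP's source-value convention where
  the source value *is* an identifier: `person_source_value` stays empty.
* **Granularity loss is visible.** The movements archetype records the
  hospital unit *and* its level-of-care category; `Visit_detail` has no
  good column for the category, so it survives in the extracts and the
  ontology but not in the CDM output — an instance of the granularity
  argument for standardizing to EN/ISO 13606 first.
* **Determinism everywhere.** Instance IRIs are keyed hashes of entry
  content (idempotent reload); the provenance timestamp is configured,
  not wall-clock (byte-identical rebuilds); exported rows are sorted by
  their pseudonymized primary key (byte-identical re-export); timestamps
  are normalized to ISO-8601 with explicit offsets, source wall-clock
  assumed Europe/Madrid.

## The synthetic source

No hospital data ships with the package; `generate_synthetic_source()`
emulates the cohort shape the pipeline was designed for: patients
attending the emergency room or hospitalized between 2020-02-17 and
2022-02-15. Defaults: 30 patients; one guaranteed episode per patient
plus a Poisson(0.8) surplus; per-episode Poisson event counts (diagnoses
2, prescriptions 1.5, administrations 1.5, movements 1.2, clinical and
laboratory observations 3 each, procedures 0.6); a 5% per-episode
limitation-of-life-sustaining-treatment probability; 10% of patients die
in their final episode. Event times are uniform within the episode span.
These sizes keep a full run under a minute on one core while every
pipeline path (all ten source entities, all mapped archetypes, death and
device derivations) is exercised; the rates are ordinary desk-scale
choices, not estimates of any real service's throughput.

What the generator does *not* emulate — comorbidity structure, plausible
dose trajectories, free-text content, coding errors beyond unmapped
codes — bounds what green tests mean: they demonstrate the
transformation contract (conservation, typing, round-trips, integrity,
anonymization), not clinical realism or performance at millions of
records.

```{r, eval = FALSE}
res <- run_pipeline(tempfile("e2o"), synth_config(seed = 1),
                    salt = "my-secret-salt")
unlist(res$export$manifest$tables)
```

## Numerical and degenerate-input conventions

Quantities are parsed as decimals and re-rendered without scientific
notation; a `QUANTITY` without a units column in the source takes the
configured constant (`"1"` for dimensionless observations). Rows whose
mandatory elements cannot be populated (empty cell, unparseable
timestamp, malformed number) are quarantined with the element and reason
— `source rows = entries + quarantined` holds exactly at every scale.
Empty stores export header-only CSVs; empty extract directories load
zero triples. Ties in derived tables are broken deterministically
(death: latest qualifying episode; ordering: radix sort on numeric
pseudonyms). The 48-bit pseudonym space makes collisions at the
10^4-identifier scale of the fixtures vanishingly unlikely, and the test
suite scans for them explicitly.

## Limitations

* The RM subset is entry/element only — no folders, compositions,
  sections, clusters, or audit/attestation structures.
* One-to-one terminology mappings; no SNOMED CT hierarchy traversal or
  cross-vocabulary inference.
* The SPARQL evaluator implements exactly the basic-graph-pattern +
  OPTIONAL fragment its own generator emits; it is not a general SPARQL
  engine, and the in-memory triple store is not a server.
* OMOP CDM is pinned at v5.4 column names; standardized vocabulary,
  health-economics and metadata table groups are out of scope.
* Multi-institution consolidation (merging exports from several sites) is
  out of scope; exports from sites sharing a salt policy would be
  join-compatible by construction, but no consolidation tooling is
  provided.
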