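# ehr2omop

Dual-model standardization of hospital EHR data: from local relational
sources to **EN/ISO 13606** normalized extracts, through a **three-layer
OWL/RDF ontology**, into **OMOP CDM** clinical tables ready for
observational research.

The package is for health-informatics teams who need their locally coded
records both *communicable without loss of meaning* (EN/ISO 13606, primary
use, identified) and *analyzable in a common data model* (OMOP CDM,
secondary use, pseudonymized) — without hard-wiring either standard into
the transformation.

## What it does

* **Archetypes** — a packaged library of twelve entry-level EN/ISO 13606
  archetypes (diagnosis, episodes, limitation of life-sustaining
  treatment, administered medication, cumulative drug dose, prescribed
  medication, movements between units, clinical observations, laboratory
  observations, patients, health problems, procedures) in a documented
  YAML dialect, with parsing, validation and round-trip serialization.
* **Terminology** — CSV mapping tables binding local codes to ICD-10-CM,
  LOINC and SNOMED CT with readable displays, plus rule-based
  categorization (e.g. hospital units → level of care). Binding is total:
  unmapped codes are preserved in system `local` and reported.
* **Extract builder** — archetype-driven ETL from source CSVs to one
  extract XML per patient and archetype (XSD shipped), with
  quarantine-not-drop semantics: `source rows = entries + quarantined`,
  exactly.
* **Ontology layers** — per archetype, a concept graph (classes and
  properties), an EN/ISO 13606 reference-model mapping
  (`rdfs:subClassOf iso13606:Entry`, RM-typed properties) and an OMOP CDM
  mapping (`omop:mapsToTable` / `omop:mapsToColumn`), as separate named
  graphs serialized to Turtle.
* **Instance store** — atomic, idempotent loading of extract entries as
  typed ontology individuals with deterministic IRIs.
* **OMOP export** — generated SPARQL SELECTs (every CDM column projected,
  mapped or not) executed against the instance graph; post-processing
  derives `Observation_period`, `Death` and `Device_exposure`,
  pseudonymizes all identifiers (keyed 48-bit HMAC, integer-rendered) and
  writes ten OMOP CDM v5.4 clinical tables as RFC 4180 CSVs with an
  integrity report and a count manifest.
* **Synthetic source** — a seeded generator emulating an ER/hospitalization
  cohort so the entire toolchain runs offline, deterministically.

## Worked example

```r
library(ehr2omop)

res <- run_pipeline("demo", synth_config(), salt = "my-secret-salt")
unlist(res$export$manifest$tables)
#> Condition_occurrence                Death      Device_exposure
#>                  116                    2                    7
#>        Drug_exposure          Measurement          Observation
#>                  233                  301                    2
#>   Observation_period               Person         Visit_detail
#>                   30                   30                   72
#>     Visit_occurrence
#>                   52
```

The default configuration simulates 30 patients over the 2020-02-17 to
2022-02-15 window. Reading the output: every source diagnosis became a
`Condition_occurrence` row; the three medication archetypes (administered,
cumulative dose, prescribed) merged into `Drug_exposure`, discriminated by
`drug_type_concept_id`; clinical and laboratory observations merged into
`Measurement`; `Person` and `Observation_period` have one row per patient,
`Death` one row per deceased patient, and `Device_exposure` holds the
device-flagged subset of procedures. `demo/omop/` contains the ten CSVs
plus `integrity_report.csv` (foreign-key orphans; empty here) and
`export_manifest.json`, whose `conservation` block shows, per archetype,
that ontology instances = exported rows + logged exclusions.

The extract-level worked example — a source row carrying a local
diagnosis code that the dictionary maps to ICD-10-CM `H40.9` (unspecified
glaucoma):

```r
built <- build_extracts(
  list(diagnoses = data.frame(
    diagnosis_id = "DG0000001", patient_id = "PAT00001",
    episode_id = "EP000001", diagnosis_code = "D003",
    recorded_at = "2021-03-01 10:30:00", source = "SAP-HIS")),
  mapping_specs()$diagnosis,
  archetype_library()[["CEN-EN13606-ENTRY.diagnosis.v1"]])
built$entries[[1]]$values$diagnosis
#> <CODED_TEXT> H40.9 [ICD-10-CM] "unspecified glaucoma"
```

After serialization, loading and export, that code arrives in
`Condition_occurrence.condition_source_value` as `H40.9`, attached to a
pseudonymized `person_id`.

## Command line

```sh
inst/cli/ehr2omop pipeline --seed 1 --n-patients 30 \
    --salt-file salt.txt --out out/
```

Subcommands `synth`, `extract`, `onto`, `load`, `export` and `validate`
run the individual stages; see the script header.

## The methods vignette

`vignettes/ehr-to-omop-methodology.Rmd` documents the model and its
assumptions, the archetype dialect, the open design decisions (mapping
axiom species, drug provenance discrimination, derived-table rules,
pseudonymization scope) and what the synthetic fixtures do and do not
demonstrate.
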