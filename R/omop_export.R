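## OMOP CDM export: execute the generated graph queries against the
## instance store, post-process the bindings into typed CDM rows
## (transformations that the queries leave to a tabular post-pass), apply
## the anonymization contract, derive the three tables that have no
## archetype of their own, and write RFC 4180 CSVs plus an integrity
## report and a count manifest. Extracts stay identified for primary use;
## everything leaving this stage is pseudonymized for secondary use.

#' Pseudonymize an identifier
#'
#' Deterministic keyed one-way transform: an HMAC-SHA-256 of the scoped
#' identifier under the export salt, truncated to 48 bits and rendered as
#' an integer (so CDM integer identifier columns keep their type). Stable
#' across tables within one export run; infeasible to invert without the
#' salt.
#'
#' @param identifier non-empty identifier string(s), already prefixed with
#'   their scope where applicable (the exporter uses `"<scope>:<id>"`).
#' @param salt non-empty secret export salt.
#' @return Character vector of integer-rendered pseudonyms.
#' @examples
#' pseudonymize("patient:PAT00001", "s3cret")
#' @export
pseudonymize <- function(identifier, salt) {
  if (!nz_string(salt) || !nzchar(salt))
    abort2("pseudonymize: empty salt", "ehr2omop_config_error")
  if (!length(identifier) || any(is.na(identifier)) || any(!nzchar(identifier)))
    abort2("pseudonymize: empty identifier", "ehr2omop_input_error")
  sprintf("%.0f", keyed_hash48(identifier, salt))
}

## Identifier scope carried by each CDM identifier column; the entry's
## own key column takes the contributing concept as scope (resolved per
## row), matching the assigning scopes used in the extracts.
column_scope <- function(column, table) {
  switch(column,
    person_id = "patient",
    visit_occurrence_id = "episode",
    visit_detail_id = "movements_between_units",
    observation_period_id = "observation_period",
    NA_character_)
}

concept_of_class <- function(cls)
  sub("^https://w3id\\.org/ehr2omop/archetype/([a-z0-9_]+)#.*$", "\\1", cls)

pk_column <- function(table) omop_schema(table)$column[1]

derive_date_columns <- function(df, schema_df) {
  for (dcol in schema_df$column[schema_df$type == "date"]) {
    src <- sub("_date$", "_datetime", dcol)
    if (dcol == "verbatim_end_date") next
    if (src %in% names(df) && all(is.na(df[[dcol]])))
      df[[dcol]] <- ifelse(is.na(df[[src]]), NA_character_, iso_date(df[[src]]))
  }
  df
}

post_process_table <- function(table, raw, cfg, salt) {
  schema_df <- omop_schema(table)
  df <- as.data.frame(raw)[, schema_df$column, drop = FALSE]
  concepts <- vapply(attr(raw, "entry_class") %||% character(0),
                     concept_of_class, character(1), USE.NAMES = FALSE)
  df <- derive_date_columns(df, schema_df)
  if (table == "Person" && nrow(df)) {
    df$year_of_birth <- substr(df$birth_datetime, 1, 4)
    df$month_of_birth <- sub("^0", "", substr(df$birth_datetime, 6, 7))
    df$day_of_birth <- sub("^0", "", substr(df$birth_datetime, 9, 10))
  }
  for (i in seq_len(nrow(schema_df))) {
    col <- schema_df$column[i]
    if (schema_df$type[i] == "concept") {
      if (col == "drug_type_concept_id" && nrow(df)) {
        tcid <- vapply(concepts, function(cn)
          as.character(cfg$concepts[[cn]]$drug_type_concept_id %||% 0L), "")
        df[[col]] <- tcid
      } else df[[col]] <- rep("0", nrow(df))
    }
    if (schema_df$type[i] == "pid" && nrow(df)) {
      scope <- column_scope(col, table)
      scoped <- if (!is.na(scope)) paste0(scope, ":", df[[col]])
                else paste0(concepts, ":", df[[col]])
      keep <- !is.na(df[[col]]) & nzchar(df[[col]])
      if (any(keep)) df[[col]][keep] <- pseudonymize(scoped[keep], salt)
    }
  }
  if (nrow(df)) {
    ord <- order(as.numeric(df[[pk_column(table)]]), method = "radix")
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

empty_table <- function(table) {
  cols <- omop_schema(table)$column
  as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
}

derive_observation_period <- function(visit_raw, cfg, salt) {
  out <- empty_table("Observation_period")
  if (!nrow(visit_raw)) return(out)
  ok <- !is.na(visit_raw$person_id)
  v <- visit_raw[ok, , drop = FALSE]
  if (!nrow(v)) return(out)
  sp <- split(v, v$person_id)
  rows <- lapply(names(sp), function(p) {
    starts <- sp[[p]]$visit_start_datetime
    ends <- c(sp[[p]]$visit_end_datetime, sp[[p]]$visit_start_datetime)
    data.frame(
      observation_period_id = pseudonymize(paste0("observation_period:", p), salt),
      person_id = pseudonymize(paste0("patient:", p), salt),
      observation_period_start_date = min(iso_date(starts[!is.na(starts)])),
      observation_period_end_date = max(iso_date(ends[!is.na(ends)])),
      period_type_concept_id =
        as.character(cfg$derived$observation_period$period_type_concept_id %||% 0L))
  })
  df <- do.call(rbind, rows)
  df[order(as.numeric(df$observation_period_id), method = "radix"), ,
     drop = FALSE]
}

derive_death <- function(visit_raw, cfg, salt) {
  out <- empty_table("Death")
  if (!nrow(visit_raw)) return(out)
  code <- cfg$derived$death$discharge_type_code %||% "DEATH"
  d <- visit_raw[!is.na(visit_raw$discharged_to_source_value) &
                   visit_raw$discharged_to_source_value == code, , drop = FALSE]
  if (!nrow(d)) return(out)
  ## at most one death per person: keep the latest qualifying episode
  d <- d[order(d$person_id, d$visit_end_datetime), , drop = FALSE]
  d <- d[!duplicated(d$person_id, fromLast = TRUE), , drop = FALSE]
  df <- data.frame(
    person_id = pseudonymize(paste0("patient:", d$person_id), salt),
    death_date = iso_date(d$visit_end_datetime),
    death_datetime = d$visit_end_datetime,
    death_type_concept_id = "0", cause_concept_id = "0",
    cause_source_value = NA_character_, cause_source_concept_id = "0")
  df[order(as.numeric(df$person_id), method = "radix"), , drop = FALSE]
}

derive_device_exposure <- function(proc_raw, cfg, salt) {
  out <- empty_table("Device_exposure")
  if (!nrow(proc_raw)) return(out)
  codes <- cfg$derived$device_exposure$device_codes %||% character(0)
  d <- proc_raw[!is.na(proc_raw$procedure_source_value) &
                  proc_raw$procedure_source_value %in% codes, , drop = FALSE]
  if (!nrow(d)) return(out)
  df <- data.frame(
    device_exposure_id = pseudonymize(paste0("procedures:",
                                             d$procedure_occurrence_id), salt),
    person_id = pseudonymize(paste0("patient:", d$person_id), salt),
    device_concept_id = "0",
    device_exposure_start_date = iso_date(d$procedure_datetime),
    device_exposure_start_datetime = d$procedure_datetime,
    device_exposure_end_date = NA_character_,
    device_exposure_end_datetime = NA_character_,
    device_type_concept_id = "0", unique_device_id = NA_character_,
    production_id = NA_character_, quantity = NA_character_,
    provider_id = NA_character_,
    visit_occurrence_id = pseudonymize(paste0("episode:",
                                              d$visit_occurrence_id), salt),
    visit_detail_id = NA_character_,
    device_source_value = d$procedure_source_value,
    device_source_concept_id = "0", unit_concept_id = "0",
    unit_source_value = NA_character_, unit_source_concept_id = "0")
  df[order(as.numeric(df$device_exposure_id), method = "radix"), , drop = FALSE]
}

integrity_check <- function(tables) {
  rows <- list()
  add <- function(table, column, value, issue)
    rows[[length(rows) + 1L]] <<- data.frame(table = table, column = column,
                                             value = value, issue = issue)
  persons <- tables$Person$person_id
  for (tab in c("Visit_occurrence", "Visit_detail", "Condition_occurrence",
                "Drug_exposure", "Measurement", "Observation", "Death",
                "Device_exposure", "Observation_period",
                "Procedure_occurrence")) {
    df <- tables[[tab]]
    if (is.null(df) || !nrow(df)) next
    bad <- unique(df$person_id[!is.na(df$person_id) &
                                 !(df$person_id %in% persons)])
    for (v in bad) add(tab, "person_id", v, "orphan person reference")
  }
  visits <- tables$Visit_occurrence$visit_occurrence_id
  vd <- tables$Visit_detail
  if (!is.null(vd) && nrow(vd)) {
    bad <- unique(vd$visit_occurrence_id[
      !is.na(vd$visit_occurrence_id) & nzchar(vd$visit_occurrence_id) &
        !(vd$visit_occurrence_id %in% visits)])
    for (v in bad) add("Visit_detail", "visit_occurrence_id", v,
                       "orphan visit reference")
  }
  if (!length(rows))
    return(data.frame(table = character(0), column = character(0),
                      value = character(0), issue = character(0)))
  do.call(rbind, rows)
}

#' Export the OMOP CDM clinical tables
#'
#' Runs the generated query of every supported table against the instance
#' store, post-processes the bindings (date derivation, concept-id
#' conventions, pseudonymization, stable ordering by pseudonymized keys),
#' derives `Observation_period`, `Death` and `Device_exposure` from the
#' configured rules, and writes one CSV per table (empty tables still get
#' their header), an `integrity_report.csv` of foreign-key orphans, and an
#' `export_manifest.json` with per-table row counts and per-archetype
#' conservation accounting.
#'
#' @param store a [triple_store()] with ontology layers and instances.
#' @param out_dir output directory.
#' @param salt non-empty pseudonymization secret.
#' @param cfg an [omop_mapping_config()].
#' @return Invisibly, a list with `tables` (named list of data frames),
#'   `integrity` (data frame), and `manifest` (list).
#' @export
export_all <- function(store, out_dir, salt, cfg = omop_mapping_config()) {
  if (!nz_string(salt) || !nzchar(salt))
    abort2("export_all: a non-empty pseudonymization salt is required",
           "ehr2omop_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  proc_on <- isTRUE(cfg$derived$procedure_occurrence_enabled)
  tables <- list()
  raws <- list()
  for (tab in c(OMOP_TABLES, "Procedure_occurrence")) {
    q <- generate_query(tab, store)
    raw <- execute_query(q, store)
    raws[[tab]] <- raw
    if (tab %in% c("Observation_period", "Death", "Device_exposure")) next
    tables[[tab]] <- post_process_table(tab, raw, cfg, salt)
  }
  visit_raw <- raws$Visit_occurrence
  proc_raw <- raws$Procedure_occurrence
  tables$Observation_period <- derive_observation_period(visit_raw, cfg, salt)
  tables$Death <- derive_death(visit_raw, cfg, salt)
  tables$Device_exposure <- derive_device_exposure(proc_raw, cfg, salt)
  n_device <- nrow(tables$Device_exposure)
  exclusions <- list()
  if (!proc_on) {
    n_excl <- nrow(proc_raw) - n_device
    tables$Procedure_occurrence <- NULL
    if (!is.na(n_excl) && n_excl > 0)
      exclusions[[length(exclusions) + 1L]] <- list(
        concept = "procedures", rows = n_excl,
        reason = "Procedure_occurrence export disabled; non-device procedure instances not exported")
  }
  emitted <- intersect(c(OMOP_TABLES, "Procedure_occurrence"), names(tables))
  for (tab in emitted)
    write_csv_rfc(tables[[tab]], file.path(out_dir, paste0(tab, ".csv")))
  integrity <- integrity_check(tables)
  write_csv_rfc(integrity, file.path(out_dir, "integrity_report.csv"))
  conservation <- lapply(names(cfg$concepts), function(cn) {
    inst <- count_instances(store, cn)
    tab <- cfg$concepts[[cn]]$omop_table
    raw <- raws[[tab]]
    cls <- concept_class_iri(cn)
    contributed <- sum((attr(raw, "entry_class") %||% character(0)) == cls)
    excluded <- 0L
    if (cn == "procedures") {
      if (proc_on) excluded <- 0L
      else { contributed <- n_device; excluded <- inst - n_device }
    }
    list(concept = cn, omop_table = if (cn == "procedures" && !proc_on)
           "Device_exposure" else tab,
         instances = inst, exported_rows = contributed,
         excluded_rows = excluded)
  })
  manifest <- list(
    tables = setNames(lapply(emitted, function(t) nrow(tables[[t]])), emitted),
    derived = list(Observation_period = nrow(tables$Observation_period),
                   Death = nrow(tables$Death),
                   Device_exposure = n_device),
    conservation = conservation,
    exclusions = exclusions,
    integrity_violations = nrow(integrity))
  jsonlite::write_json(manifest, file.path(out_dir, "export_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tables = tables, integrity = integrity, manifest = manifest))
}
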