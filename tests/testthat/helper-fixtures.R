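# Shared fixtures: cached end-to-end runs (built once per session) and the
# single-row glaucoma source used by the worked-example tests.

e2e_cache <- new.env()

# "small": unit-scale run; "full": the default study-scale configuration.
e2e_run <- function(key = "small") {
  if (!is.null(e2e_cache[[key]])) return(e2e_cache[[key]])
  res <- switch(key,
    small = run_pipeline(file.path(tempdir(), "e2o-small"),
                         synth_config(seed = 42L, n_patients = 8L),
                         salt = "unit-salt"),
    full = run_pipeline(file.path(tempdir(), "e2o-full"),
                        synth_config(), salt = "study-salt"))
  e2e_cache[[key]] <- res
  res
}

empty_source_tables <- function() {
  specs <- mapping_specs()
  gen <- generate_synthetic_source(synth_config(seed = 1L, n_patients = 1L))
  lapply(gen$tables, function(df) df[0, , drop = FALSE])
}

# One patient with one episode carrying the local glaucoma code D003
# (ICD-10-CM H40.9 in the packaged dictionary).
glaucoma_source <- function() {
  src <- empty_source_tables()
  src$patients <- data.frame(
    patient_id = "PAT99001", sex_code = "SEX-F",
    birth_date = "1950-06-15", source = "SAP-HIS")
  src$episodes <- data.frame(
    episode_id = "EP990001", patient_id = "PAT99001", episode_type = "HOSP",
    admitted_at = "2021-03-01 09:00:00", discharged_at = "2021-03-05 12:00:00",
    discharge_type = "HOME", source = "SAP-HIS")
  src$diagnoses <- data.frame(
    diagnosis_id = "DG9900001", patient_id = "PAT99001",
    episode_id = "EP990001", diagnosis_code = "D003",
    recorded_at = "2021-03-01 10:30:00", source = "SAP-HIS")
  src
}

write_source_dir <- function(src, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(src))
    ehr2omop:::write_csv_rfc(src[[nm]], file.path(dir, paste0(nm, ".csv")))
  dir
}

glaucoma_run <- function() {
  if (!is.null(e2e_cache$glaucoma)) return(e2e_cache$glaucoma)
  dir <- file.path(tempdir(), "e2o-glaucoma-src")
  write_source_dir(glaucoma_source(), dir)
  res <- run_pipeline(file.path(tempdir(), "e2o-glaucoma"),
                      source_dir = dir, salt = "fig-salt")
  e2e_cache$glaucoma <- res
  res
}

read_omop_csv <- function(res, table) {
  read.csv(file.path(res$paths$omop, paste0(table, ".csv")),
           colClasses = "character", check.names = FALSE)
}

# Independent count of the triples one parsed entry should contribute.
oracle_entry_triples <- function(entry) {
  n <- 1L  # typing
  for (dv in entry$values) {
    n <- n + switch(dv$kind,
      CODED_TEXT = 4L + (!is.null(dv$display)),
      QUANTITY = 4L,
      IDENTIFIER = 4L,
      1L)
  }
  n
}
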