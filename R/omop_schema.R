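## OMOP Common Data Model v5.4 — the ten standardized clinical-data tables
## served by the exporter, plus Procedure_occurrence which can be enabled
## in the mapping configuration. Column order follows the CDM DDL; types
## are the subset needed for CSV emission ("pid" marks an identifier
## column that is pseudonymized on export).

OMOP_TABLES <- c("Condition_occurrence", "Death", "Device_exposure",
                 "Drug_exposure", "Measurement", "Observation",
                 "Observation_period", "Person", "Visit_detail",
                 "Visit_occurrence")

omop_schema_def <- function() {
  cols <- function(...) {
    x <- c(...)
    data.frame(column = names(x), type = unname(x))
  }
  list(
    Person = cols(
      person_id = "pid", gender_concept_id = "concept",
      year_of_birth = "integer", month_of_birth = "integer",
      day_of_birth = "integer", birth_datetime = "datetime",
      race_concept_id = "concept", ethnicity_concept_id = "concept",
      location_id = "integer", provider_id = "integer",
      care_site_id = "integer", person_source_value = "string",
      gender_source_value = "string", gender_source_concept_id = "concept",
      race_source_value = "string", race_source_concept_id = "concept",
      ethnicity_source_value = "string", ethnicity_source_concept_id = "concept"),
    Observation_period = cols(
      observation_period_id = "pid", person_id = "pid",
      observation_period_start_date = "date",
      observation_period_end_date = "date",
      period_type_concept_id = "concept"),
    Visit_occurrence = cols(
      visit_occurrence_id = "pid", person_id = "pid",
      visit_concept_id = "concept", visit_start_date = "date",
      visit_start_datetime = "datetime", visit_end_date = "date",
      visit_end_datetime = "datetime", visit_type_concept_id = "concept",
      provider_id = "integer", care_site_id = "integer",
      visit_source_value = "string", visit_source_concept_id = "concept",
      admitted_from_concept_id = "concept", admitted_from_source_value = "string",
      discharged_to_concept_id = "concept", discharged_to_source_value = "string",
      preceding_visit_occurrence_id = "pid"),
    Visit_detail = cols(
      visit_detail_id = "pid", person_id = "pid",
      visit_detail_concept_id = "concept", visit_detail_start_date = "date",
      visit_detail_start_datetime = "datetime", visit_detail_end_date = "date",
      visit_detail_end_datetime = "datetime",
      visit_detail_type_concept_id = "concept", provider_id = "integer",
      care_site_id = "integer", visit_detail_source_value = "string",
      visit_detail_source_concept_id = "concept",
      admitted_from_concept_id = "concept", admitted_from_source_value = "string",
      discharged_to_source_value = "string", discharged_to_concept_id = "concept",
      preceding_visit_detail_id = "pid", parent_visit_detail_id = "pid",
      visit_occurrence_id = "pid"),
    Condition_occurrence = cols(
      condition_occurrence_id = "pid", person_id = "pid",
      condition_concept_id = "concept", condition_start_date = "date",
      condition_start_datetime = "datetime", condition_end_date = "date",
      condition_end_datetime = "datetime",
      condition_type_concept_id = "concept",
      condition_status_concept_id = "concept", stop_reason = "string",
      provider_id = "integer", visit_occurrence_id = "pid",
      visit_detail_id = "pid", condition_source_value = "string",
      condition_source_concept_id = "concept",
      condition_status_source_value = "string"),
    Drug_exposure = cols(
      drug_exposure_id = "pid", person_id = "pid",
      drug_concept_id = "concept", drug_exposure_start_date = "date",
      drug_exposure_start_datetime = "datetime",
      drug_exposure_end_date = "date", drug_exposure_end_datetime = "datetime",
      verbatim_end_date = "date", drug_type_concept_id = "concept",
      stop_reason = "string", refills = "integer", quantity = "decimal",
      days_supply = "integer", sig = "string", route_concept_id = "concept",
      lot_number = "string", provider_id = "integer",
      visit_occurrence_id = "pid", visit_detail_id = "pid",
      drug_source_value = "string", drug_source_concept_id = "concept",
      route_source_value = "string", dose_unit_source_value = "string"),
    Measurement = cols(
      measurement_id = "pid", person_id = "pid",
      measurement_concept_id = "concept", measurement_date = "date",
      measurement_datetime = "datetime", measurement_time = "string",
      measurement_type_concept_id = "concept", operator_concept_id = "concept",
      value_as_number = "decimal", value_as_concept_id = "concept",
      unit_concept_id = "concept", range_low = "decimal",
      range_high = "decimal", provider_id = "integer",
      visit_occurrence_id = "pid", visit_detail_id = "pid",
      measurement_source_value = "string",
      measurement_source_concept_id = "concept", unit_source_value = "string",
      unit_source_concept_id = "concept", value_source_value = "string",
      measurement_event_id = "integer", meas_event_field_concept_id = "concept"),
    Observation = cols(
      observation_id = "pid", person_id = "pid",
      observation_concept_id = "concept", observation_date = "date",
      observation_datetime = "datetime",
      observation_type_concept_id = "concept", value_as_number = "decimal",
      value_as_string = "string", value_as_concept_id = "concept",
      qualifier_concept_id = "concept", unit_concept_id = "concept",
      provider_id = "integer", visit_occurrence_id = "pid",
      visit_detail_id = "pid", observation_source_value = "string",
      observation_source_concept_id = "concept", unit_source_value = "string",
      qualifier_source_value = "string", value_source_value = "string",
      observation_event_id = "integer", obs_event_field_concept_id = "concept"),
    Death = cols(
      person_id = "pid", death_date = "date", death_datetime = "datetime",
      death_type_concept_id = "concept", cause_concept_id = "concept",
      cause_source_value = "string", cause_source_concept_id = "concept"),
    Device_exposure = cols(
      device_exposure_id = "pid", person_id = "pid",
      device_concept_id = "concept", device_exposure_start_date = "date",
      device_exposure_start_datetime = "datetime",
      device_exposure_end_date = "date",
      device_exposure_end_datetime = "datetime",
      device_type_concept_id = "concept", unique_device_id = "string",
      production_id = "string", quantity = "decimal",
      provider_id = "integer", visit_occurrence_id = "pid",
      visit_detail_id = "pid", device_source_value = "string",
      device_source_concept_id = "concept", unit_concept_id = "concept",
      unit_source_value = "string", unit_source_concept_id = "concept"),
    Procedure_occurrence = cols(
      procedure_occurrence_id = "pid", person_id = "pid",
      procedure_concept_id = "concept", procedure_date = "date",
      procedure_datetime = "datetime", procedure_end_date = "date",
      procedure_end_datetime = "datetime",
      procedure_type_concept_id = "concept", modifier_concept_id = "concept",
      quantity = "decimal", provider_id = "integer",
      visit_occurrence_id = "pid", visit_detail_id = "pid",
      procedure_source_value = "string",
      procedure_source_concept_id = "concept",
      modifier_source_value = "string"))
}

#' OMOP CDM table schemas
#'
#' Returns the column schema of the supported OMOP CDM v5.4 clinical
#' tables: the ten standardized clinical-data tables exported by default
#' (`Condition_occurrence`, `Death`, `Device_exposure`, `Drug_exposure`,
#' `Measurement`, `Observation`, `Observation_period`, `Person`,
#' `Visit_detail`, `Visit_occurrence`) plus `Procedure_occurrence`, which
#' is export-optional.
#'
#' @param table optional table name; with `NULL` the full named list is
#'   returned.
#' @return A data frame with columns `column`, `type` (one of `pid`,
#'   `concept`, `integer`, `decimal`, `string`, `date`, `datetime`), or a
#'   named list of such data frames.
#' @examples
#' names(omop_schema())
#' head(omop_schema("Person"))
#' @export
omop_schema <- function(table = NULL) {
  def <- omop_schema_def()
  if (is.null(table)) return(def)
  if (!table %in% names(def))
    abort2(paste0("unknown OMOP table ", dQuote(table), "; supported: ",
                  paste(OMOP_TABLES, collapse = ", ")), "ehr2omop_config_error")
  def[[table]]
}
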