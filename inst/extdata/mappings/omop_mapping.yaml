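# Archetype <-> OMOP CDM correspondence and per-element column bindings.
# An element may feed several columns (facets resolved by the exporter:
# coded values contribute their code to *_source_value columns, quantities
# their magnitude to numeric columns and their units to unit columns).
# The three drug archetypes all map to Drug_exposure and are discriminated
# by drug_type_concept_id. concept_id columns are otherwise emitted as 0
# (no standard-vocabulary resolution is performed).
concepts:
  patients:
    omop_table: Person
    columns:
      patient_id: person_id
      sex: gender_source_value
      birth_date: birth_datetime
  episodes:
    omop_table: Visit_occurrence
    columns:
      episode_id: visit_occurrence_id
      patient_id: person_id
      episode_type: visit_source_value
      admission_datetime: visit_start_datetime
      discharge_datetime: visit_end_datetime
      discharge_type: discharged_to_source_value
  diagnosis:
    omop_table: Condition_occurrence
    columns:
      diagnosis_id: condition_occurrence_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      diagnosis: condition_source_value
      diagnosis_datetime: condition_start_datetime
  administered_medication:
    omop_table: Drug_exposure
    drug_type_concept_id: 32818
    columns:
      administration_id: drug_exposure_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      drug: drug_source_value
      administration_datetime: drug_exposure_start_datetime
      dose: [quantity, dose_unit_source_value]
      route: route_source_value
  cumulative_drug_dose:
    omop_table: Drug_exposure
    drug_type_concept_id: 32880
    columns:
      administration_id: drug_exposure_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      drug: drug_source_value
      administration_datetime: drug_exposure_start_datetime
      cumulative_dose: [quantity, dose_unit_source_value]
  prescribed_medication:
    omop_table: Drug_exposure
    drug_type_concept_id: 32838
    columns:
      prescription_id: drug_exposure_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      drug: drug_source_value
      start_datetime: drug_exposure_start_datetime
      end_datetime: drug_exposure_end_datetime
      dose: [quantity, dose_unit_source_value]
      route: route_source_value
  movements_between_units:
    omop_table: Visit_detail
    columns:
      movement_id: visit_detail_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      unit: visit_detail_source_value
      entry_datetime: visit_detail_start_datetime
      exit_datetime: visit_detail_end_datetime
  clinical_observations:
    omop_table: Measurement
    columns:
      observation_id: measurement_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      observation: measurement_source_value
      value: [value_as_number, unit_source_value]
      observation_datetime: measurement_datetime
  laboratory_observations:
    omop_table: Measurement
    columns:
      lab_id: measurement_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      analyte: measurement_source_value
      value: [value_as_number, unit_source_value]
      lab_datetime: measurement_datetime
  limitation_life_sustaining_treatment:
    omop_table: Observation
    columns:
      llst_id: observation_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      llst_status: observation_source_value
      llst_datetime: observation_datetime
  procedures:
    omop_table: Procedure_occurrence
    columns:
      procedure_id: procedure_occurrence_id
      patient_id: person_id
      episode_id: visit_occurrence_id
      procedure: procedure_source_value
      procedure_datetime: procedure_datetime
derived:
  procedure_occurrence_enabled: false
  death:
    from: episodes
    discharge_type_code: DEATH
  observation_period:
    from: episodes
    period_type_concept_id: 32817
  device_exposure:
    from: procedures
    device_codes: ["392230005", "447365002"]
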