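# Bindings from the synthetic hospital source schema (one CSV per entity)
# to the archetype elements. Transforms: bind_code (terminology binding),
# categorize (rule-table categorization), datetime_parse (local wall-clock
# -> ISO-8601 with offset), identity (default). IDENTIFIER elements carry
# a scope naming the identifier namespace; QUANTITY elements take their
# units from units_column.
diagnosis:
  archetype_id: CEN-EN13606-ENTRY.diagnosis.v1
  source_table: diagnoses
  key_element: diagnosis_id
  elements:
    episode_id: {column: episode_id, scope: episode}
    diagnosis: {column: diagnosis_code, transform: bind_code, local_system: HIS-DIAG}
    diagnosis_datetime: {column: recorded_at, transform: datetime_parse}
    patient_id: {column: patient_id, scope: patient}
    diagnosis_id: {column: diagnosis_id, scope: diagnosis}
    source: {column: source}
patients:
  archetype_id: CEN-EN13606-ENTRY.patients.v1
  source_table: patients
  key_element: patient_id
  elements:
    patient_id: {column: patient_id, scope: patient}
    sex: {column: sex_code, transform: bind_code, local_system: HIS-SEX}
    birth_date: {column: birth_date, transform: datetime_parse}
    source: {column: source}
episodes:
  archetype_id: CEN-EN13606-ENTRY.episodes.v1
  source_table: episodes
  key_element: episode_id
  elements:
    episode_id: {column: episode_id, scope: episode}
    patient_id: {column: patient_id, scope: patient}
    episode_type: {column: episode_type, transform: bind_code, local_system: HIS-EPI}
    admission_datetime: {column: admitted_at, transform: datetime_parse}
    discharge_datetime: {column: discharged_at, transform: datetime_parse}
    discharge_type: {column: discharge_type, transform: bind_code, local_system: HIS-DISCH}
    source: {column: source}
limitation_life_sustaining_treatment:
  archetype_id: CEN-EN13606-ENTRY.limitation_life_sustaining_treatment.v1
  source_table: llst
  key_element: llst_id
  elements:
    llst_id: {column: llst_id, scope: limitation_life_sustaining_treatment}
    patient_id: {column: patient_id, scope: patient}
    episode_id: {column: episode_id, scope: episode}
    llst_status: {column: llst_code, transform: bind_code, local_system: HIS-LLST}
    llst_datetime: {column: recorded_at, transform: datetime_parse}
    source: {column: source}
administered_medication:
  archetype_id: CEN-EN13606-ENTRY.administered_medication.v1
  source_table: drug_administrations
  key_element: administration_id
  elements:
    administration_id: {column: administration_id, scope: administered_medication}
    patient_id: {column: patient_id, scope: patient}
    episode_id: {column: episode_id, scope: episode}
    drug: {column: drug_code, transform: bind_code, local_system: HIS-DRUG}
    administration_datetime: {column: administered_at, transform: datetime_parse}
    dose: {column: dose, units_column: dose_units}
    route: {column: route, transform: bind_code, local_system: HIS-ROUTE}
    source: {column: source}
cumulative_drug_dose:
  archetype_id: CEN-EN13606-ENTRY.cumulative_drug_dose.v1
  source_table: drug_administrations
  key_element: administration_id
  elements:
    administration_id: {column: administration_id, scope: cumulative_drug_dose}
    patient_id: {column: patient_id, scope: patient}
    episode_id: {column: episode_id, scope: episode}
    drug: {column: drug_code, transform: bind_code, local_system: HIS-DRUG}
    administration_datetime: {column: administered_at, transform: datetime_parse}
    cumulative_dose: {column: cumulative_dose, units_column: dose_units}
    source: {column: source}
prescribed_medication:
  archetype_id: CEN-EN13606-ENTRY.prescribed_medication.v1
  source_table: drug_prescriptions
  key_element: prescription_id
  elements:
    prescription_id: {column: prescription_id, scope: prescribed_medication}
    patient_id: {column: patient_id, scope: patient}
    episode_id: {column: episode_id, scope: episode}
    drug: {column: drug_code, transform: bind_code, local_system: HIS-DRUG}
    start_datetime: {column: start_at, transform: datetime_parse}
    end_datetime: {column: end_at, transform: datetime_parse}
    dose: {column: dose, units_column: dose_units}
    route: {column: route, transform: bind_code, local_system: HIS-ROUTE}
    source: {column: source}
movements_between_units:
  archetype_id: CEN-EN13606-ENTRY.movements_between_units.v1
  source_table: movements
  key_element: movement_id
  elements:
    movement_id: {column: movement_id, scope: movements_between_units}
    patient_id: {column: patient_id, scope: patient}
    episode_id: {column: episode_id, scope: episode}
    unit: {column: unit_code, transform: bind_code, local_system: HIS-UNIT}
    level_of_care: {column: unit_code, transform: categorize, dimension: level_of_care}
    entry_datetime: {column: entered_at, transform: datetime_parse}
    exit_datetime: {column: exited_at, transform: datetime_parse}
    source: {column: source}
clinical_observations:
  archetype_id: CEN-EN13606-ENTRY.clinical_observations.v1
  source_table: clinical_observations
  key_element: observation_id
  elements:
    observation_id: {column: observation_id, scope: clinical_observations}
    patient_id: {column: patient_id, scope: patient}
    episode_id: {column: episode_id, scope: episode}
    observation: {column: observation_code, transform: bind_code, local_system: HIS-CLIN}
    value: {column: value, units_column: units}
    observation_datetime: {column: observed_at, transform: datetime_parse}
    source: {column: source}
laboratory_observations:
  archetype_id: CEN-EN13606-ENTRY.laboratory_observations.v1
  source_table: laboratory_observations
  key_element: lab_id
  elements:
    lab_id: {column: lab_id, scope: laboratory_observations}
    patient_id: {column: patient_id, scope: patient}
    episode_id: {column: episode_id, scope: episode}
    analyte: {column: analyte_code, transform: bind_code, local_system: HIS-LAB}
    value: {column: value, units_column: units}
    lab_datetime: {column: resulted_at, transform: datetime_parse}
    source: {column: source}
procedures:
  archetype_id: CEN-EN13606-ENTRY.procedures.v1
  source_table: procedures
  key_element: procedure_id
  elements:
    procedure_id: {column: procedure_id, scope: procedures}
    patient_id: {column: patient_id, scope: patient}
    episode_id: {column: episode_id, scope: episode}
    procedure: {column: procedure_code, transform: bind_code, local_system: HIS-PROC}
    procedure_datetime: {column: performed_at, transform: datetime_parse}
    source: {column: source}
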