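# Laboratory observation entry. Reconstructed element list; maps to OMOP
# Measurement.
archetype_id: CEN-EN13606-ENTRY.laboratory_observations.v1
version: "1"
language: es
description: >
  One laboratory result with a numeric value and units, coded with LOINC.
entry:
  name: Laboratory observation
  elements:
    - node_id: lab_id
      name: Laboratory result ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: patient_id
      name: Patient ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: episode_id
      name: Episode ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: analyte
      name: Analyte
      kind: CODED_TEXT
      mandatory: true
      terminology: LOINC
    - node_id: value
      name: Result value
      kind: QUANTITY
      mandatory: true
    - node_id: lab_datetime
      name: Result date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
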