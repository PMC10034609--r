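# Clinical observation entry (vital signs and bedside measurements).
# Reconstructed element list; maps to OMOP Measurement.
archetype_id: CEN-EN13606-ENTRY.clinical_observations.v1
version: "1"
language: es
description: >
  One clinical (bedside) observation with a numeric value and units,
  coded with LOINC.
entry:
  name: Clinical observation
  elements:
    - node_id: observation_id
      name: Observation ID
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
    - node_id: observation
      name: Observed property
      kind: CODED_TEXT
      mandatory: true
      terminology: LOINC
    - node_id: value
      name: Observed value
      kind: QUANTITY
      mandatory: true
    - node_id: observation_datetime
      name: Observation date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
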