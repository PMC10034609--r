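# Episode entry (one ER or hospitalization episode). Reconstructed element
# list; maps to OMOP Visit_occurrence.
archetype_id: CEN-EN13606-ENTRY.episodes.v1
version: "1"
language: es
description: >
  One care episode (emergency room attendance or hospitalization) of a
  patient, with admission/discharge times and discharge disposition.
entry:
  name: Episode
  elements:
    - node_id: episode_id
      name: Episode ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: patient_id
      name: Patient ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: episode_type
      name: Episode type
      kind: CODED_TEXT
      mandatory: true
      terminology: local
    - node_id: admission_datetime
      name: Admission date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: discharge_datetime
      name: Discharge date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: discharge_type
      name: Discharge disposition
      kind: CODED_TEXT
      mandatory: true
      terminology: local
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
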