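# Limitation of life-sustaining treatment entry. Reconstructed element
# list; maps to OMOP Observation.
archetype_id: CEN-EN13606-ENTRY.limitation_life_sustaining_treatment.v1
version: "1"
language: es
description: >
  A recorded decision to limit life-sustaining treatment for a patient
  within an episode.
entry:
  name: Limitation of life-sustaining treatment
  elements:
    - node_id: llst_id
      name: Record ID
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
    - node_id: llst_status
      name: Limitation status
      kind: CODED_TEXT
      mandatory: true
      terminology: SNOMED CT
    - node_id: llst_datetime
      name: Decision date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
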