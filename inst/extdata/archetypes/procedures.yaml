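# Procedure entry. Reconstructed element list; maps to OMOP
# Procedure_occurrence (with a device subset routed to Device_exposure).
archetype_id: CEN-EN13606-ENTRY.procedures.v1
version: "1"
language: es
description: >
  One procedure performed on a patient within an episode, coded with
  SNOMED CT.
entry:
  name: Procedure
  elements:
    - node_id: procedure_id
      name: Procedure ID
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
    - node_id: procedure
      name: Procedure
      kind: CODED_TEXT
      mandatory: true
      terminology: SNOMED CT
    - node_id: procedure_datetime
      name: Procedure date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
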