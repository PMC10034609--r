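# Prescribed medication entry. Reconstructed element list; maps to OMOP
# Drug_exposure.
archetype_id: CEN-EN13606-ENTRY.prescribed_medication.v1
version: "1"
language: es
description: >
  One drug prescription issued during an episode.
entry:
  name: Prescribed medication
  elements:
    - node_id: prescription_id
      name: Prescription ID
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
    - node_id: drug
      name: Drug
      kind: CODED_TEXT
      mandatory: true
      terminology: SNOMED CT
    - node_id: start_datetime
      name: Prescription start
      kind: DATE_TIME
      mandatory: true
    - node_id: end_datetime
      name: Prescription end
      kind: DATE_TIME
      mandatory: false
    - node_id: dose
      name: Prescribed dose
      kind: QUANTITY
      mandatory: false
    - node_id: route
      name: Route of administration
      kind: CODED_TEXT
      mandatory: false
      terminology: local
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
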