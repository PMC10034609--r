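# Diagnosis entry (the worked example of the archetype library): one coded
# diagnosis recorded within a clinical episode. Element set follows the
# canonical structure of the concept: 6 elements.
archetype_id: CEN-EN13606-ENTRY.diagnosis.v1
version: "1"
language: es
description: >
  One coded diagnosis recorded for a patient within a clinical episode,
  bound to ICD-10-CM.
entry:
  name: Diagnosis
  elements:
    - node_id: episode_id
      name: Episode ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: diagnosis
      name: Diagnosis
      kind: CODED_TEXT
      mandatory: true
      terminology: ICD-10-CM
    - node_id: diagnosis_datetime
      name: Diagnosis date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: patient_id
      name: Patient ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: diagnosis_id
      name: Diagnosis ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
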