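# Patient entry. Element list reconstructed from the concept's OMOP Person
# correspondence.
archetype_id: CEN-EN13606-ENTRY.patients.v1
version: "1"
language: es
description: >
  Administrative and demographic record of one patient.
entry:
  name: Patient
  elements:
    - node_id: patient_id
      name: Patient ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: sex
      name: Administrative sex
      kind: CODED_TEXT
      mandatory: true
      terminology: SNOMED CT
    - node_id: birth_date
      name: Date of birth
      kind: DATE_TIME
      mandatory: true
    - node_id: death_datetime
      name: Date and time of death
      kind: DATE_TIME
      mandatory: false
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
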