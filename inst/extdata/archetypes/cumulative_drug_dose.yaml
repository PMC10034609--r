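# Cumulative drug dose entry: running total of a drug administered to a
# patient up to an administration event. Reconstructed element list; maps
# to OMOP Drug_exposure.
archetype_id: CEN-EN13606-ENTRY.cumulative_drug_dose.v1
version: "1"
language: es
description: >
  Cumulative dose of a drug administered to a patient up to and including
  one administration event.
entry:
  name: Cumulative drug dose
  elements:
    - node_id: administration_id
      name: Administration ID
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
    - node_id: administration_datetime
      name: Administration date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: cumulative_dose
      name: Cumulative dose
      kind: QUANTITY
      mandatory: true
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
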