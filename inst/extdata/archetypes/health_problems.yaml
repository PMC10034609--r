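# Health problems entry. Included to complete the twelve-concept library;
# its upstream source is free text processed outside this toolchain, so no
# extract pipeline is wired to it here.
archetype_id: CEN-EN13606-ENTRY.health_problems.v1
version: "1"
language: es
description: >
  A health problem of a patient recognized from clinical narrative,
  coded with SNOMED CT. No structured extract pipeline is provided.
entry:
  name: Health problem
  elements:
    - node_id: problem_id
      name: Problem ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: patient_id
      name: Patient ID
      kind: IDENTIFIER
      mandatory: true
    - node_id: problem
      name: Health problem
      kind: CODED_TEXT
      mandatory: true
      terminology: SNOMED CT
    - node_id: onset_datetime
      name: Onset date and time
      kind: DATE_TIME
      mandatory: false
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
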