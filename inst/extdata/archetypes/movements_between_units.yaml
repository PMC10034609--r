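# Movements-between-units entry: a stay in one hospital unit within an
# episode, with the unit categorized by level of care. Reconstructed
# element list; maps to OMOP Visit_detail.
archetype_id: CEN-EN13606-ENTRY.movements_between_units.v1
version: "1"
language: es
description: >
  One stay of a patient in a hospital unit within an episode.
entry:
  name: Movement between units
  elements:
    - node_id: movement_id
      name: Movement ID
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
    - node_id: unit
      name: Hospital unit
      kind: CODED_TEXT
      mandatory: true
      terminology: local
    - node_id: level_of_care
      name: Level of care
      kind: SIMPLE_TEXT
      mandatory: true
    - node_id: entry_datetime
      name: Unit entry date and time
      kind: DATE_TIME
      mandatory: true
    - node_id: exit_datetime
      name: Unit exit date and time
      kind: DATE_TIME
      mandatory: false
    - node_id: source
      name: Source system
      kind: SIMPLE_TEXT
      mandatory: false
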