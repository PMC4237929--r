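{
  "name": "ASAV (Amberg-Schwandorf Algorithm for Primary Triage, reconstructed)",
  "root": "death_check",
  "nodes": [
    { "id": "death_check", "predicate": "death_signs_present",
      "branches": { "yes": "dead", "no": "bleeding_check" } },
    { "id": "dead", "assign": "black" },
    { "id": "bleeding_check", "predicate": "spurting_haemorrhage",
      "actions": ["indicate_bleeding_lsi"], "next": "walk_check" },
    { "id": "walk_check", "predicate": "can_walk",
      "branches": { "yes": "minor", "no": "consciousness_check" } },
    { "id": "minor", "assign": "green" },
    { "id": "consciousness_check", "predicate": "unconscious",
      "branches": { "yes": "airway_lsi", "no": "breathing_check" } },
    { "id": "airway_lsi", "actions": ["indicate_airway_lsi"],
      "next": "immediate_unconscious" },
    { "id": "immediate_unconscious", "assign": "red" },
    { "id": "breathing_check", "predicate": "breathing_disorder_or_apnoea",
      "branches": { "yes": "immediate_breathing", "no": "circulation_check" } },
    { "id": "immediate_breathing", "assign": "red" },
    { "id": "circulation_check", "predicate": "circulation_abnormal",
      "branches": { "yes": "immediate_circulation", "no": "delayed" } },
    { "id": "immediate_circulation", "assign": "red" },
    { "id": "delayed", "assign": "yellow" }
  ]
}
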