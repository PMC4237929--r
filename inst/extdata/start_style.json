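{
  "name": "START-style comparator (synthetic; walking assessed first, black only on definite signs of death)",
  "root": "death_check",
  "nodes": [
    { "id": "death_check", "predicate": "death_signs_present",
      "branches": { "yes": "dead", "no": "walk_check" } },
    { "id": "dead", "assign": "black" },
    { "id": "walk_check", "predicate": "can_walk",
      "branches": { "yes": "minor", "no": "bleeding_check" } },
    { "id": "minor", "assign": "green" },
    { "id": "bleeding_check", "predicate": "spurting_haemorrhage",
      "actions": ["indicate_bleeding_lsi"], "next": "breathing_check" },
    { "id": "breathing_check", "predicate": "breathing_disorder_or_apnoea",
      "branches": { "yes": "immediate_breathing", "no": "consciousness_check" } },
    { "id": "immediate_breathing", "assign": "red" },
    { "id": "consciousness_check", "predicate": "unconscious",
      "branches": { "yes": "airway_lsi", "no": "circulation_check" } },
    { "id": "airway_lsi", "actions": ["indicate_airway_lsi"],
      "next": "immediate_unconscious" },
    { "id": "immediate_unconscious", "assign": "red" },
    { "id": "circulation_check", "predicate": "circulation_abnormal",
      "branches": { "yes": "immediate_circulation", "no": "delayed" } },
    { "id": "immediate_circulation", "assign": "red" },
    { "id": "delayed", "assign": "yellow" }
  ]
}
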