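{
  "n_recommendations": 358,
  "n_rules": 405,
  "n_variables": 116,
  "n_unique_conditions": 208,
  "rules_per_recommendation": {
    "1": 341,
    "2": 1,
    "3": 2,
    "4": 14
  },
  "vars_per_rule": {
    "1": 34,
    "2": 106,
    "3": 96,
    "4": 68,
    "5": 38,
    "6": 33,
    "7": 17,
    "8": 10,
    "9": 3
  },
  "variable_usage_buckets": {
    "1": 31,
    "2-3": 35,
    "4-10": 30,
    ">10": 20
  },
  "condition_reuse_buckets": {
    "1": 156,
    "2-3": 44,
    "4+": 8
  },
  "max_condition_reuse": 62,
  "priority_mix": [47, 102, 120, 90, 46],
  "source_priority_mix": [165, 142, 51],
  "note": "Structural (not clinical) profile of the full-scale knowledge base; see full_kb_structure_config()."
}
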