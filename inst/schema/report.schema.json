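{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "occubiome pipeline report",
  "type": "object",
  "required": ["package", "version", "parameters", "n_samples", "n_features",
               "alpha", "anosim", "lefse_flagged"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "parameters": {
      "type": "object",
      "required": ["seed", "min_prevalence", "gate_alpha", "lda_threshold",
                   "n_permutations", "n_forests", "n_trees"],
      "properties": {
        "seed": {"type": "integer"},
        "min_prevalence": {"type": "number"},
        "gate_alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
        "lda_threshold": {"type": "number"},
        "n_permutations": {"type": "integer", "minimum": 99},
        "n_forests": {"type": "integer", "minimum": 1},
        "n_trees": {"type": "integer", "minimum": 1}
      }
    },
    "n_samples": {"type": "integer", "minimum": 1},
    "n_features": {"type": "integer", "minimum": 1},
    "alpha": {"type": "array"},
    "anosim": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["R", "p_value"],
        "properties": {
          "R": {"type": "number", "minimum": -1, "maximum": 1},
          "p_value": {"type": "number", "exclusiveMinimum": 0, "maximum": 1}
        }
      }
    },
    "lefse_flagged": {"type": "object"},
    "classifier": {"type": ["object", "null"]}
  }
}
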