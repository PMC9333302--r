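{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "rs-report.schema.json",
  "title": "reproscore run report",
  "type": "object",
  "required": ["version", "timestamp", "seed", "dataset", "config",
               "full_data_biomarkers", "estimates"],
  "properties": {
    "version": {"type": "string"},
    "timestamp": {"type": "string"},
    "seed": {"type": "integer"},
    "dataset": {
      "type": "object",
      "required": ["n", "n_plus", "n_minus", "r", "feature_kind"],
      "properties": {
        "n": {"type": "integer", "minimum": 2},
        "n_plus": {"type": "integer", "minimum": 1},
        "n_minus": {"type": "integer", "minimum": 1},
        "r": {"type": "integer", "minimum": 1},
        "feature_kind": {"enum": ["continuous", "genotype"]}
      }
    },
    "config": {
      "type": "object",
      "required": ["test", "alpha", "mcc"],
      "properties": {
        "test": {"enum": ["t", "welch"]},
        "alpha": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "mcc": {"enum": ["BH", "bonferroni", "none"]}
      }
    },
    "full_data_biomarkers": {
      "type": "object",
      "required": ["count", "ids"],
      "properties": {
        "count": {"type": "integer", "minimum": 0},
        "ids": {"type": "array", "items": {"type": "string"}}
      }
    },
    "estimates": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["method", "k", "mean", "sd", "seed",
                     "per_iteration", "child_seeds"],
        "properties": {
          "method": {"enum": ["oRS", "uRS", "bRS", "RS_hat", "RS_star"]},
          "k": {"type": "integer", "minimum": 1},
          "mean": {"type": "number", "minimum": 0, "maximum": 1},
          "sd": {"type": "number", "minimum": 0},
          "seed": {"type": "integer"},
          "per_iteration": {
            "type": "array",
            "items": {"type": "number", "minimum": 0, "maximum": 1}
          },
          "child_seeds": {"type": "array", "items": {"type": "integer"}}
        }
      }
    },
    "subset_curve": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["subset_size", "k", "mean", "sd", "per_iteration"],
        "properties": {
          "subset_size": {"type": "integer", "minimum": 4},
          "k": {"type": "integer", "minimum": 1},
          "mean": {"type": "number", "minimum": 0, "maximum": 1},
          "sd": {"type": "number", "minimum": 0},
          "per_iteration": {
            "type": "array",
            "items": {"type": "number", "minimum": 0, "maximum": 1}
          }
        }
      }
    }
  }
}
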