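{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "wescohort cohort report",
  "type": "object",
  "required": ["tool", "note", "groups", "msi_h_counts", "samples",
               "comparisons", "spectrum"],
  "properties": {
    "tool": {"type": "string"},
    "note": {"type": "string"},
    "groups": {
      "type": "object",
      "additionalProperties": {"type": "array", "items": {"type": "string"}}
    },
    "msi_h_counts": {
      "type": "object",
      "additionalProperties": {"type": "number", "minimum": 0}
    },
    "samples": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sample_id"],
        "properties": {
          "sample_id": {"type": "string"},
          "tmb": {"type": ["number", "null"]},
          "math": {"type": ["number", "null"]},
          "msi_status": {"type": ["string", "null"],
                         "enum": ["MSI-H", "MSS", "QNS", null]},
          "n_gain": {"type": ["integer", "null"]},
          "n_loss": {"type": ["integer", "null"]},
          "cnv_burden": {"type": ["number", "null"],
                         "minimum": 0, "maximum": 1},
          "cni": {"type": ["number", "null"]}
        }
      }
    },
    "comparisons": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["metric", "group_a", "group_b", "p_value"],
        "properties": {
          "metric": {"type": "string"},
          "group_a": {"type": "string"},
          "group_b": {"type": "string"},
          "statistic": {"type": ["number", "null"]},
          "p_value": {"type": ["number", "null"],
                      "minimum": 0, "maximum": 1}
        }
      }
    },
    "spectrum": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["group_a", "group_b", "dominant_class_a",
                     "dominant_class_b", "titv_p"],
        "properties": {
          "dominant_class_a": {"type": "string"},
          "dominant_class_b": {"type": "string"},
          "titv_p": {"type": ["number", "null"]}
        }
      }
    }
  }
}
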