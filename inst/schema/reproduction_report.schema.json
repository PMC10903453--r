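{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cristamorph reproduction report",
  "type": "object",
  "required": ["package", "config", "species", "comparisons"],
  "properties": {
    "package": {"const": "cristamorph"},
    "config": {"type": "object"},
    "species": {
      "type": "object",
      "minProperties": 1,
      "additionalProperties": {
        "type": "object",
        "required": [
          "dimer_angle_deg", "stalk_sep_nm", "inter_dimer_nm",
          "yaw_offset_deg", "wedge_angle_deg", "sa_to_v_per_nm",
          "mean_width_nm", "n_cristae"
        ],
        "properties": {
          "dimer_angle_deg": {"$ref": "#/definitions/recovery"},
          "stalk_sep_nm": {"$ref": "#/definitions/recovery"},
          "inter_dimer_nm": {"$ref": "#/definitions/recovery"},
          "yaw_offset_deg": {"$ref": "#/definitions/recovery"},
          "wedge_angle_deg": {"$ref": "#/definitions/recovery"},
          "mean_width_nm": {"$ref": "#/definitions/recovery"},
          "sa_to_v_per_nm": {
            "type": "object",
            "required": ["measured"],
            "properties": {"measured": {"type": "number"}}
          },
          "n_cristae": {"type": "integer", "minimum": 1}
        }
      }
    },
    "comparisons": {
      "type": "object",
      "properties": {
        "sa_to_v": {"$ref": "#/definitions/comparison"},
        "width": {"$ref": "#/definitions/comparison"}
      }
    },
    "errors": {"type": "object"}
  },
  "definitions": {
    "recovery": {
      "type": "object",
      "required": ["measured", "ground_truth", "abs_error"],
      "properties": {
        "measured": {"type": "number"},
        "ground_truth": {"type": "number"},
        "abs_error": {"type": "number", "minimum": 0}
      }
    },
    "comparison": {
      "type": "object",
      "required": ["fold_change", "p_value", "stars"],
      "properties": {
        "fold_change": {"type": "number"},
        "p_value": {"type": "number", "minimum": 0, "maximum": 1},
        "stars": {"enum": ["ns", "*", "**", "***", "****"]}
      }
    }
  }
}
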