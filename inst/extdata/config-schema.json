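{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fcnf pipeline configuration",
  "type": "object",
  "required": ["design", "feedback", "simulate", "stats", "seed"],
  "additionalProperties": false,
  "properties": {
    "design": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "fixation_len": {"type": "integer", "minimum": 0,
          "description": "fixation volumes at the start of each run"},
        "n_pairs": {"type": "integer", "minimum": 1,
          "description": "number of (fc-NF, no-NF) mini-block pairs per run"},
        "fcnf_len": {"type": "integer", "minimum": 1,
          "description": "fc-NF mini-block length in volumes"},
        "nonf_len": {"type": "integer", "minimum": 1,
          "description": "no-NF mini-block length in volumes"},
        "n_runs": {"type": "integer", "minimum": 1}
      }
    },
    "feedback": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "implementation": {"enum": ["negative", "weighted_negative", "positive"]},
        "upper_bound": {"type": "number",
          "description": "correlation mapped to the full thermometer; nonzero (-1, -0.3 or +1 for the three implementations)"},
        "n_segments": {"type": "integer", "minimum": 1},
        "frozen_segment": {"type": "integer", "minimum": 1,
          "description": "segment shown throughout no-NF mini-blocks"},
        "window_length": {"type": "integer", "minimum": 3,
          "description": "moving correlation window length in volumes"}
      }
    },
    "simulate": {
      "type": "object",
      "description": "cohort generator settings; keys mirror the cohort_params() arguments (n_subjects required, covariate moments, link coefficients, subject-level parameter moments, AR and nuisance settings)",
      "required": ["n_subjects"]
    },
    "stats": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "bootstrap_B": {"type": "integer", "minimum": 100},
        "outlier_threshold": {"type": "number",
          "description": "squared Mahalanobis distance cutoff (default: chi-square(2) 0.975 quantile)"},
        "fisher_variant": {"enum": ["z", "t"]},
        "slope_scope": {"enum": ["all", "fcnf_only", "nonf_only"]},
        "correction": {"enum": ["none", "BH"]}
      }
    },
    "seed": {"type": "integer"}
  }
}
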