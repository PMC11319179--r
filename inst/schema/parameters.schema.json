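{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "screencea parameter bundle",
  "description": "Complete parameter set for one screening cost-effectiveness analysis setting (urban or rural). All monetary values are USD; CNY inputs are converted at costs.currency_rate before storage. All probabilities are annual.",
  "type": "object",
  "required": ["setting", "strategies", "transitions", "costs", "utilities",
               "missed_hr", "discount", "wtp", "baseline_population",
               "horizon_age", "cycle_length"],
  "properties": {
    "setting": {
      "type": "object",
      "required": ["label", "prevalence"],
      "properties": {
        "label": {"enum": ["urban", "rural"]},
        "prevalence": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1,
          "description": "prevalence of undiagnosed type 2 diabetes"},
        "rural_hr": {"type": "object",
          "description": "hazard-ratio multipliers keyed by destination health state; must be absent or all 1.0 for urban",
          "additionalProperties": {"type": "number", "exclusiveMinimum": 0}}
      }
    },
    "strategies": {
      "type": "object",
      "description": "keyed by strategy name (POCT_HBA1C, VENOUS_HBA1C, FCG)",
      "additionalProperties": {
        "type": "object",
        "required": ["name", "sensitivity", "specificity",
                     "cost_direct_medical", "cost_direct_nonmedical",
                     "cost_indirect"],
        "properties": {
          "name": {"type": "string"},
          "sensitivity": {"type": "number", "minimum": 0, "maximum": 1},
          "specificity": {"type": "number", "minimum": 0, "maximum": 1},
          "cut_point_text": {"type": "string"},
          "cost_direct_medical": {"type": "number", "minimum": 0},
          "cost_direct_nonmedical": {"type": "number", "minimum": 0},
          "cost_indirect": {"type": "number", "minimum": 0}
        }
      }
    },
    "transitions": {
      "type": "object",
      "description": "long-format annual transition probabilities; rows per (from_state, age_band) must sum to 1 within 1e-6 (renormalized on load); age bands may be a single [18,80] band (age-constant) or any ordered partition",
      "required": ["from_state", "to_state", "age_low", "age_high", "probability"],
      "properties": {
        "from_state": {"type": "array", "items": {"type": "string"}},
        "to_state": {"type": "array", "items": {"type": "string"}},
        "age_low": {"type": "array", "items": {"type": "number"}},
        "age_high": {"type": "array", "items": {"type": "number"}},
        "probability": {"type": "array",
          "items": {"type": "number", "minimum": 0, "maximum": 1}}
      }
    },
    "costs": {
      "type": "object",
      "required": ["state_annual_cost", "ogtt_cost"],
      "properties": {
        "state_annual_cost": {"type": "object",
          "description": "USD per year per health state (direct medical only for complication states); DEATH must be 0",
          "additionalProperties": {"type": "number", "minimum": 0}},
        "ogtt_cost": {"type": "number", "minimum": 0},
        "currency_rate": {"type": "number", "exclusiveMinimum": 0,
          "description": "CNY per USD, default 6.4 (informational)"}
      }
    },
    "utilities": {
      "type": "object",
      "required": ["state_utility"],
      "properties": {
        "state_utility": {"type": "object",
          "description": "QALY weight per year per health state, in [0,1]; DEATH must be 0; expected ordering NON_DM >= DM_NO_COMP >= complication states (warning only)",
          "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}}
      }
    },
    "missed_hr": {
      "type": "object",
      "required": ["hr_micro", "hr_macro", "hr_death"],
      "properties": {
        "hr_micro": {"type": "number", "exclusiveMinimum": 0, "default": 1.391},
        "hr_macro": {"type": "number", "exclusiveMinimum": 0, "default": 1.287},
        "hr_death": {"type": "number", "exclusiveMinimum": 0, "default": 1.290}
      }
    },
    "discount": {
      "type": "object",
      "properties": {
        "rate": {"type": "number", "minimum": 0, "maximum": 1, "default": 0.05},
        "sensitivity_range": {"type": "array", "items": {"type": "number"},
          "minItems": 2, "maxItems": 2, "default": [0.0, 0.08]}
      }
    },
    "wtp": {
      "type": "object",
      "description": "lambda must equal multiplier * gdp_per_capita",
      "properties": {
        "lambda": {"type": "number", "default": 37653},
        "gdp_per_capita": {"type": "number", "default": 12551},
        "multiplier": {"type": "integer", "default": 3}
      }
    },
    "baseline_population": {
      "type": "object",
      "description": "columns age (years, in [18, horizon_age]), sex, weight (sums to 1)",
      "required": ["age", "sex", "weight"]
    },
    "horizon_age": {"type": "number", "default": 80},
    "cycle_length": {"const": 1}
  }
}
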