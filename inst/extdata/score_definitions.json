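[
  {
    "name": "alvarado",
    "items": {
      "tenderness_rlq": 2,
      "rebound_tenderness": 1,
      "wbc_high": 2,
      "nausea_vomiting": 1,
      "anorexia": 1,
      "migration_of_pain": 1,
      "fever": 1,
      "neutrophilia": 1
    },
    "positivity_cutoff": 5,
    "threshold_policy": {
      "wbc_cutoff": 11,
      "neutrophilia_abs_cutoff": 7.9,
      "neutrophilia_pct_cutoff": 75,
      "crp_cutoff": 20,
      "temp_cutoff": 38.5
    }
  },
  {
    "name": "pas",
    "items": {
      "tenderness_rlq": 2,
      "cough_hop_tenderness": 2,
      "wbc_high": 1,
      "nausea_vomiting": 1,
      "anorexia": 1,
      "migration_of_pain": 1,
      "fever": 1,
      "neutrophilia": 1
    },
    "positivity_cutoff": 6,
    "threshold_policy": {
      "wbc_cutoff": 11,
      "neutrophilia_abs_cutoff": 7.9,
      "neutrophilia_pct_cutoff": 75,
      "crp_cutoff": 20,
      "temp_cutoff": 38.5
    }
  },
  {
    "name": "tzanakis",
    "items": {
      "tenderness_rlq": 4,
      "rebound_tenderness": 3,
      "wbc_high": 2,
      "us_appendicitis": 6
    },
    "positivity_cutoff": 8,
    "threshold_policy": {
      "wbc_cutoff": 11,
      "neutrophilia_abs_cutoff": 7.9,
      "neutrophilia_pct_cutoff": 75,
      "crp_cutoff": 20,
      "temp_cutoff": 38.5
    }
  },
  {
    "name": "has",
    "items": {
      "tenderness_rlq": 1,
      "rebound_tenderness": 1,
      "us_appendicitis": 1,
      "continuous_pain": 1
    },
    "positivity_cutoff": 3,
    "threshold_policy": {
      "wbc_cutoff": 11,
      "neutrophilia_abs_cutoff": 7.9,
      "neutrophilia_pct_cutoff": 75,
      "crp_cutoff": 20,
      "temp_cutoff": 38.5
    }
  },
  {
    "name": "mhas",
    "items": {
      "tenderness_rlq": 1,
      "rebound_tenderness": 1,
      "wbc_high": 1,
      "crp_high": 1,
      "us_appendicitis": 1
    },
    "positivity_cutoff": 3,
    "threshold_policy": {
      "wbc_cutoff": 11,
      "neutrophilia_abs_cutoff": 7.9,
      "neutrophilia_pct_cutoff": 75,
      "crp_cutoff": 20,
      "temp_cutoff": 38.5
    }
  },
  {
    "name": "ai",
    "items": {
      "rebound_tenderness": 1,
      "wbc_high": 1,
      "crp_high": 1,
      "us_appendicitis": 1
    },
    "positivity_cutoff": 2,
    "threshold_policy": {
      "wbc_cutoff": 11,
      "neutrophilia_abs_cutoff": 7.9,
      "neutrophilia_pct_cutoff": 75,
      "crp_cutoff": 20,
      "temp_cutoff": 38.5
    }
  }
]
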