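{
  "_comment": "Standard SOFA component cutoffs (Vincent 1996 tiers). direction 'low': score = number of cuts the value falls strictly below; 'high': number of cuts the value meets or exceeds. Cardiovascular combines MAP with any administered vasopressor from the lexicon (dose-free tiers via cv_tier).",
  "coagulation":    {"variable": "platelets",       "source": "low",  "direction": "low",  "cuts": [150, 100, 50, 20]},
  "liver":          {"variable": "bilirubin_total", "source": "high", "direction": "high", "cuts": [1.2, 2.0, 6.0, 12.0]},
  "renal":          {"variable": "creatinine",      "source": "high", "direction": "high", "cuts": [1.2, 2.0, 3.5, 5.0]},
  "cardiovascular": {"map_variable": "map", "map_cut": 70}
}
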