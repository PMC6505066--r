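{
  "_comment": "Adult Sepsis Event surveillance parameters (CDC toolkit defaults, config-exposed). window_days is the +/- window around the blood-culture day for both the first qualifying antibiotic day and the organ-dysfunction criteria. min_qad is the minimum run of consecutive qualifying antibiotic days (or until discharge/death if earlier).",
  "window_days": 2,
  "min_qad": 4,
  "organ_dysfunction": {
    "vasopressor_initiation": true,
    "mechanical_ventilation": true,
    "lactate_threshold": 2.0,
    "platelet_threshold": 100,
    "platelet_decline": 0.5,
    "creatinine_ratio": 2.0,
    "bilirubin_ratio": 2.0,
    "bilirubin_min": 2.0
  }
}
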