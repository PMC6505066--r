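{
  "_comment": "Starter drug lexicon: search tokens are matched case-insensitively as substrings across all name fields; exclusion tokens veto a record entirely. cv_tier is the cardiovascular SOFA tier assigned when the agent is administered (dose rates are not parsed; see vignette). Antibiotic class/route grouping is an editable standard-classes seed, not a transcription of any appendix.",
  "exclusion_tokens": ["research", "study"],
  "route_groups": {
    "systemic-IV": ["IV", "IVPB", "IV PUSH", "INTRAVENOUS", "IM", "INTRAMUSCULAR"],
    "systemic-oral": ["PO", "ORAL", "NG", "G-TUBE", "PER TUBE", "SL"],
    "non-systemic": ["TOPICAL", "OPHTHALMIC", "OTIC", "NASAL", "INHALED", "INHALATION", "RECTAL", "VAGINAL", "IRRIGATION"]
  },
  "drugs": [
    {"name": "norepinephrine", "tokens": ["norepinephrine", "levophed"], "category": "vasoactive", "cv_tier": 3},
    {"name": "epinephrine",    "tokens": ["epinephrine", "adrenalin"],   "not_tokens": ["norepinephrine", "noradrenalin"], "category": "vasoactive", "cv_tier": 3},
    {"name": "dopamine",       "tokens": ["dopamine"],                   "category": "vasoactive", "cv_tier": 3},
    {"name": "dobutamine",     "tokens": ["dobutamine"],                 "category": "vasoactive", "cv_tier": 2},
    {"name": "vasopressin",    "tokens": ["vasopressin"],                "category": "vasoactive", "cv_tier": 3},
    {"name": "phenylephrine",  "tokens": ["phenylephrine", "neosynephrine"], "category": "vasoactive", "cv_tier": 3},
    {"name": "milrinone",      "tokens": ["milrinone"],                  "category": "vasoactive", "cv_tier": 3},
    {"name": "propofol",       "tokens": ["propofol", "diprivan"],       "category": "sedative"},
    {"name": "midazolam",      "tokens": ["midazolam", "versed"],        "category": "sedative"},
    {"name": "dexmedetomidine","tokens": ["dexmedetomidine", "precedex"],"category": "sedative"},
    {"name": "fentanyl",       "tokens": ["fentanyl"],                   "category": "analgesic"},
    {"name": "morphine",       "tokens": ["morphine"],                   "category": "analgesic"},
    {"name": "hydromorphone",  "tokens": ["hydromorphone", "dilaudid"],  "category": "analgesic"},
    {"name": "cisatracurium",  "tokens": ["cisatracurium", "nimbex"],    "category": "paralytic"},
    {"name": "vecuronium",     "tokens": ["vecuronium"],                 "category": "paralytic"},
    {"name": "vancomycin",     "tokens": ["vancomycin"],   "category": "antibiotic", "abx_class": "glycopeptide"},
    {"name": "piperacillin-tazobactam", "tokens": ["piperacillin", "zosyn"], "category": "antibiotic", "abx_class": "penicillin"},
    {"name": "cefepime",       "tokens": ["cefepime"],     "category": "antibiotic", "abx_class": "cephalosporin"},
    {"name": "ceftriaxone",    "tokens": ["ceftriaxone", "rocephin"], "category": "antibiotic", "abx_class": "cephalosporin"},
    {"name": "levofloxacin",   "tokens": ["levofloxacin", "levaquin"], "category": "antibiotic", "abx_class": "fluoroquinolone"},
    {"name": "ciprofloxacin",  "tokens": ["ciprofloxacin", "cipro"],  "category": "antibiotic", "abx_class": "fluoroquinolone"},
    {"name": "metronidazole",  "tokens": ["metronidazole", "flagyl"], "category": "antibiotic", "abx_class": "nitroimidazole"},
    {"name": "azithromycin",   "tokens": ["azithromycin", "zithromax"], "category": "antibiotic", "abx_class": "macrolide"},
    {"name": "meropenem",      "tokens": ["meropenem"],    "category": "antibiotic", "abx_class": "carbapenem"},
    {"name": "mupirocin",      "tokens": ["mupirocin", "bactroban"], "category": "antibiotic", "abx_class": "topical-antibacterial"},
    {"name": "rifaximin",      "tokens": ["rifaximin", "xifaxan"],   "category": "other"},
    {"name": "furosemide",     "tokens": ["furosemide", "lasix"],    "category": "other"},
    {"name": "insulin",        "tokens": ["insulin"],                "category": "other"}
  ]
}
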