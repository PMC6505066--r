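{
  "_comment": "Standard test definitions: 16 laboratory tests and 6 vital signs. LOINC sets, synonym patterns, topography filters, plausible ranges and unit conversions are editable implementer defaults seeded from clinically standard values; they are NOT transcriptions of any site-specific list. Conversions map reported unit -> canonical as value*slope + intercept.",
  "labs": {
    "albumin": {
      "canonical_unit": "g/dL", "plausible_range": [0.5, 8],
      "loinc_set": ["1751-7"], "name_patterns": ["albumin", "alb"],
      "topography_filter": ["serum", "plasma", "blood"],
      "conversions": {"g/dL": [1, 0], "g/L": [0.1, 0]}
    },
    "bilirubin_total": {
      "canonical_unit": "mg/dL", "plausible_range": [0, 60],
      "loinc_set": ["1975-2", "42719-5"], "name_patterns": ["total bilirubin", "bilirubin total", "t bili", "tbili", "bilirubin"],
      "topography_filter": ["serum", "plasma", "blood"],
      "conversions": {"mg/dL": [1, 0], "umol/L": [0.058467, 0]}
    },
    "bun": {
      "canonical_unit": "mg/dL", "plausible_range": [1, 250],
      "loinc_set": ["3094-0"], "name_patterns": ["urea nitrogen", "bun"],
      "topography_filter": ["serum", "plasma", "blood"],
      "conversions": {"mg/dL": [1, 0], "mmol/L": [2.8011, 0]}
    },
    "bicarbonate": {
      "canonical_unit": "mmol/L", "plausible_range": [2, 60],
      "loinc_set": ["1963-8", "2028-9"], "name_patterns": ["bicarbonate", "hco3", "co2", "carbon dioxide"],
      "topography_filter": ["serum", "plasma", "blood", "arterial blood", "venous blood"],
      "conversions": {"mmol/L": [1, 0], "mEq/L": [1, 0]}
    },
    "chloride": {
      "canonical_unit": "mmol/L", "plausible_range": [60, 160],
      "loinc_set": ["2075-0"], "name_patterns": ["chloride", "cl"],
      "topography_filter": ["serum", "plasma", "blood"],
      "conversions": {"mmol/L": [1, 0], "mEq/L": [1, 0]}
    },
    "creatinine": {
      "canonical_unit": "mg/dL", "plausible_range": [0.1, 40],
      "loinc_set": ["2160-0", "38483-4"], "name_patterns": ["creatinine", "creat"],
      "topography_filter": ["serum", "plasma", "blood"],
      "conversions": {"mg/dL": [1, 0], "umol/L": [0.011312, 0]}
    },
    "glucose": {
      "canonical_unit": "mg/dL", "plausible_range": [10, 2000],
      "loinc_set": ["2345-7", "2339-0"], "name_patterns": ["glucose", "glu"],
      "topography_filter": ["serum", "plasma", "blood"],
      "conversions": {"mg/dL": [1, 0], "mmol/L": [18.016, 0]}
    },
    "hematocrit": {
      "canonical_unit": "%", "plausible_range": [5, 75],
      "loinc_set": ["4544-3", "20570-8"], "name_patterns": ["hematocrit", "hct"],
      "topography_filter": ["blood", "whole blood"],
      "conversions": {"%": [1, 0], "fraction": [100, 0]}
    },
    "hemoglobin": {
      "canonical_unit": "g/dL", "plausible_range": [1, 25],
      "loinc_set": ["718-7"], "name_patterns": ["hemoglobin", "hgb"],
      "topography_filter": ["blood", "whole blood"],
      "conversions": {"g/dL": [1, 0], "g/L": [0.1, 0]}
    },
    "lactate": {
      "canonical_unit": "mmol/L", "plausible_range": [0.1, 30],
      "loinc_set": ["2524-7", "32693-4"], "name_patterns": ["lactate", "lactic acid"],
      "topography_filter": ["serum", "plasma", "blood", "arterial blood", "venous blood"],
      "conversions": {"mmol/L": [1, 0], "mg/dL": [0.111, 0]}
    },
    "platelets": {
      "canonical_unit": "10*3/uL", "plausible_range": [1, 2000],
      "loinc_set": ["777-3"], "name_patterns": ["platelet", "plt"],
      "topography_filter": ["blood", "whole blood"],
      "conversions": {"10*3/uL": [1, 0], "K/uL": [1, 0], "10*9/L": [1, 0]}
    },
    "potassium": {
      "canonical_unit": "mmol/L", "plausible_range": [1, 12],
      "loinc_set": ["2823-3"], "name_patterns": ["potassium"],
      "topography_filter": ["serum", "plasma", "blood"],
      "conversions": {"mmol/L": [1, 0], "mEq/L": [1, 0]}
    },
    "sodium": {
      "canonical_unit": "mmol/L", "plausible_range": [90, 200],
      "loinc_set": ["2951-2"], "name_patterns": ["sodium", "na+"],
      "topography_filter": ["serum", "plasma", "blood"],
      "conversions": {"mmol/L": [1, 0], "mEq/L": [1, 0]}
    },
    "wbc": {
      "canonical_unit": "10*3/uL", "plausible_range": [0.05, 300],
      "loinc_set": ["6690-2", "26464-8"], "name_patterns": ["white blood cell", "wbc", "leukocyte"],
      "topography_filter": ["blood", "whole blood"],
      "conversions": {"10*3/uL": [1, 0], "K/uL": [1, 0], "10*9/L": [1, 0]}
    },
    "inr": {
      "canonical_unit": "ratio", "plausible_range": [0.5, 20],
      "loinc_set": ["6301-6", "34714-6"], "name_patterns": ["inr", "international normalized ratio"],
      "topography_filter": ["plasma", "blood"],
      "conversions": {"ratio": [1, 0], "": [1, 0]}
    },
    "ph": {
      "canonical_unit": "pH", "plausible_range": [6.5, 8.0],
      "loinc_set": ["2744-1", "11558-4"], "name_patterns": ["ph"],
      "topography_filter": ["arterial blood", "venous blood", "blood"],
      "conversions": {"pH": [1, 0], "": [1, 0]}
    }
  },
  "vitals": {
    "temperature": {
      "vital_types": ["TEMPERATURE", "TEMP"],
      "canonical_unit": "C", "plausible_range": [25, 45],
      "conversions": {"C": [1, 0], "F": [0.5555555555555556, -17.77777777777778]}
    },
    "heart_rate": {
      "vital_types": ["PULSE", "HEART RATE", "HR"],
      "canonical_unit": "bpm", "plausible_range": [10, 300],
      "conversions": {"bpm": [1, 0], "/min": [1, 0]}
    },
    "respiratory_rate": {
      "vital_types": ["RESPIRATION", "RESPIRATORY RATE", "RR"],
      "canonical_unit": "/min", "plausible_range": [1, 80],
      "conversions": {"/min": [1, 0]}
    },
    "systolic_bp": {
      "vital_types": ["SYSTOLIC BP", "SBP"],
      "canonical_unit": "mmHg", "plausible_range": [20, 300],
      "conversions": {"mmHg": [1, 0]}
    },
    "diastolic_bp": {
      "vital_types": ["DIASTOLIC BP", "DBP"],
      "canonical_unit": "mmHg", "plausible_range": [5, 200],
      "conversions": {"mmHg": [1, 0]}
    },
    "map": {
      "vital_types": ["MAP", "MEAN ARTERIAL PRESSURE"],
      "canonical_unit": "mmHg", "plausible_range": [10, 250],
      "conversions": {"mmHg": [1, 0]}
    }
  },
  "events": {
    "blood_culture": {
      "loinc_set": ["600-7"],
      "name_patterns": ["blood culture", "blood cx", "culture, blood"],
      "topography_filter": ["blood", "whole blood"]
    }
  }
}
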