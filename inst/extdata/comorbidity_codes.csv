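comorbidity,icd_version,prefix
congestive_heart_failure,9,428
congestive_heart_failure,10,I50
cardiac_arrhythmia,9,427
cardiac_arrhythmia,10,I49
valvular_disease,9,424
valvular_disease,10,I35
pulmonary_circulation,9,4160
pulmonary_circulation,10,I27
peripheral_vascular,9,443
peripheral_vascular,10,I73
hypertension_uncomplicated,9,401
hypertension_uncomplicated,10,I10
hypertension_complicated,9,402
hypertension_complicated,10,I11
paralysis,9,344
paralysis,10,G81
other_neurological,9,332
other_neurological,10,G20
chronic_pulmonary,9,496
chronic_pulmonary,10,J44
diabetes_uncomplicated,9,2500
diabetes_uncomplicated,10,E119
diabetes_complicated,9,2504
diabetes_complicated,10,E112
hypothyroidism,9,244
hypothyroidism,10,E03
renal_failure,9,585
renal_failure,10,N18
liver_disease,9,571
liver_disease,10,K70
peptic_ulcer,9,533
peptic_ulcer,10,K27
aids_hiv,9,042
aids_hiv,10,B20
lymphoma,9,202
lymphoma,10,C85
metastatic_cancer,9,197
metastatic_cancer,10,C78
solid_tumor,9,162
solid_tumor,10,C34
rheumatoid_arthritis,9,714
rheumatoid_arthritis,10,M05
coagulopathy,9,286
coagulopathy,10,D68
obesity,9,2780
obesity,10,E66
weight_loss,9,783
weight_loss,10,R63
fluid_electrolyte,9,276
fluid_electrolyte,10,E87
deficiency_anemia,9,280
deficiency_anemia,10,D50
alcohol_abuse,9,3039
alcohol_abuse,10,F10
drug_abuse,9,3049
drug_abuse,10,F19
psychoses,9,295
psychoses,10,F20
depression,9,311
depression,10,F33
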