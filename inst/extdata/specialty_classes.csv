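specialty_code,acute,icu
MICU,TRUE,TRUE
SICU,TRUE,TRUE
CCU,TRUE,TRUE
CSICU,TRUE,TRUE
NEURO ICU,TRUE,TRUE
ICU,TRUE,TRUE
MED,TRUE,FALSE
WARD,TRUE,FALSE
SURG,TRUE,FALSE
TELE,TRUE,FALSE
CARD,TRUE,FALSE
NEURO,TRUE,FALSE
ORTHO,TRUE,FALSE
GI,TRUE,FALSE
ONC,TRUE,FALSE
CLC,FALSE,FALSE
NHCU,FALSE,FALSE
DOM,FALSE,FALSE
REHAB,FALSE,FALSE
PSYCH RES,FALSE,FALSE
HOSPICE,FALSE,FALSE
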