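icd_version,prefix,category
10,A,infectious
10,B,infectious
10,C,oncologic
10,D,hematologic
10,E,endocrine
10,F,psychiatric
10,G,neurologic
10,I,cardiovascular
10,J,respiratory
10,K,gastrointestinal
10,L,dermatologic
10,M,musculoskeletal
10,N,renal_genitourinary
10,R,symptoms_signs
10,S,injury
10,T,injury
9,00,infectious
9,01,infectious
9,02,infectious
9,03,infectious
9,1,oncologic
9,2,endocrine
9,29,psychiatric
9,3,neurologic
9,4,cardiovascular
9,48,respiratory
9,49,respiratory
9,5,gastrointestinal
9,58,renal_genitourinary
9,59,renal_genitourinary
9,7,symptoms_signs
9,8,injury
9,9,injury
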