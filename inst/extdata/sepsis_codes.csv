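list_name,icd_version,code
angus_infection,9,0380
angus_infection,9,0389
angus_infection,9,481
angus_infection,9,486
angus_infection,9,5990
angus_infection,9,56211
angus_infection,9,68110
angus_infection,10,A400
angus_infection,10,A419
angus_infection,10,J13
angus_infection,10,J189
angus_infection,10,N390
angus_infection,10,K5732
angus_infection,10,L03011
angus_organ_dysfunction,9,51881
angus_organ_dysfunction,9,5845
angus_organ_dysfunction,9,5849
angus_organ_dysfunction,9,570
angus_organ_dysfunction,9,2875
angus_organ_dysfunction,9,4589
angus_organ_dysfunction,9,34830
angus_organ_dysfunction,10,J9600
angus_organ_dysfunction,10,N170
angus_organ_dysfunction,10,N179
angus_organ_dysfunction,10,K720
angus_organ_dysfunction,10,D696
angus_organ_dysfunction,10,I959
angus_organ_dysfunction,10,G9340
angus_explicit,9,99592
angus_explicit,9,78552
angus_explicit,10,R6520
angus_explicit,10,R6521
ventilation_procedure,9,9670
ventilation_procedure,9,9671
ventilation_procedure,9,9672
ventilation_procedure,10,5A1935Z
ventilation_procedure,10,5A1945Z
ventilation_procedure,10,5A1955Z
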