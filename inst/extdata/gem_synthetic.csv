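source,target,direction
99592,R6520,forward
78552,R6521,forward
0389,A419,forward
5990,N390,forward
51881,J9600,forward
5849,N179,forward
R6520,99592,backward
R6521,78552,backward
A419,0389,backward
A409,0389,backward
N390,5990,backward
J9600,51881,backward
N179,5849,backward
N170,5845,backward
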