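construct,condition,percent_dimer,sem,n
C349A,apyrase control,2.1,0.86,3
C349A,MTS-2-MTS,0.78,0.41,3
C349A,BMB,0.8,0.54,3
C349A,BM(PEG)2,0.6,0.19,3
G30C C349A,MTS-2-MTS,31.2,4.9,3
G30C C349A,BMB 1 min,46,7,3
G30C C349A,BMB 30 min,53,4,3
G30C C349A,BMB surface fraction,44,9,6
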