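peptide_code,concentration_ng_ml,mean_percent,sem,n
EPL001,0.1,0.56,0.56,4
EPL001,1,0.30,0.30,4
EPL001,10,0,0,4
EPL001,100,0.09,0.05,4
EPL001,1000,0,0,4
FNNI,100,2.7,NA,4
FNNI,1000,3.5,NA,4
KEFNNI,100,29.53,9.69,8
KEFNNI,10000,4.7,2.4,3
MKPVFNNI,100,44.40,11.85,8
MKPVFNNI,10000,3.92,1.97,3
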