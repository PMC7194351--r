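peptide_code,sequence,blocks
EPL001,MKPLTGKVKEFNNI,yes
RSGII20,DEDDVYKTNNIAYEDVVGGE,no
FLY20,KRSKEQKKNNISHHNYKLKN,no
EPL122,MLKTGEKPVKFNNIKGLEQF,no
EPL142,MLKTGEKPVKFNNI,yes
EPL143,MLKTGEKPVFKNNI,yes
EPL801,MKPVFNNI,yes
EPL373,MLKTGEKPN,no
EPL601,MKPVFN,no
EPL030,KLKMNGKNIEPVFT,no
EPL536,KEFNNI,yes
EPL545,EFNNI,yes
GKV,GKV,no
KVK,KVK,no
VKE,VKE,no
KEF,KEF,no
EFN,EFN,no
FNN,FNN,no
NNI,NNI,yes
FNNI,FNNI,yes
FNNA,FNNA,yes
FNAI,FNAI,yes
FANI,FANI,yes
ANNI,ANNI,highest-conc-only
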