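label,residue_tag,atom_descriptor
a,K9,nitrogen in the side-chain of K9
b,E10,delta carbon in E
c,E10,hydroxyl oxygen in the side-chain of E
d,F11,beta carbon in F
e,F11,gamma carbon of F
f,I14,peptide bond carbon of I
g,I14,delta carbon of I
h,N13,gamma carbon of N13
i,N13,nitrogen of the side-chain of N13
j,N12,peptide bond carbon of N12
k,N12,nitrogen of side-chain of N12
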