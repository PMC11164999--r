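group,dTc,dPc,dTb,n_atoms,description
CH3,0.0141,-0.0012,23.58,4,non-ring -CH3
CH2,0.0189,0.0000,22.88,3,non-ring -CH2-
CH,0.0164,0.0020,21.74,2,non-ring >CH-
C,0.0067,0.0043,18.25,1,non-ring >C<
ACH,0.0082,0.0011,26.73,2,aromatic ring =CH-
AC,0.0143,0.0008,31.01,1,aromatic ring =C<
OH,0.0741,0.0112,92.88,2,alcohol -OH
COOH,0.0791,0.0077,169.09,4,carboxylic acid -COOH
NH2,0.0243,0.0109,73.23,3,primary amine -NH2
NH,0.0295,0.0077,50.17,2,non-ring secondary amine >NH
F,0.0111,-0.0057,-0.03,1,fluorine -F
Cl,0.0105,-0.0049,38.13,1,chlorine -Cl
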