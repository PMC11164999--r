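group,w,description
CH3,0.29602,alkyl -CH3
CH2,0.14691,alkyl -CH2-
CH,-0.00530,alkyl >CH-
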