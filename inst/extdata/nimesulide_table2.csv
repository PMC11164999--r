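# solute: nimesulide
# M_solute: 308.31
T_K,P_bar,y2,u_y
312,160,3.22e-5,
312,190,5.18e-5,
312,220,7.53e-5,
331,160,3.92e-5,
331,190,7.19e-5,
331,220,9.95e-5,
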