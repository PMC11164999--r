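# solute: nimesulide
# M_solute: 308.31
T_K,P_bar,y2,u_y
312,160,3.18e-5,
312,190,5.11e-5,
312,220,7.42e-5,
331,160,3.80e-5,
331,190,7.08e-5,
331,220,9.85e-5,
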