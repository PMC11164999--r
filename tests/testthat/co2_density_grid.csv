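T_K,P_bar,rho_kg_m3
308.15,120,767.0721644970
308.15,160,827.1711915972
308.15,200,865.7222074529
308.15,240,894.8763003251
308.15,280,918.6356205028
308.15,320,938.8429428536
308.15,360,956.5106966974
308.15,400,972.2604731682
318.15,120,657.7369212868
318.15,160,759.9818953631
318.15,200,812.6872474073
318.15,240,849.3945366073
318.15,280,878.0004346692
318.15,320,901.6525011872
318.15,360,921.9323887779
318.15,400,939.7527072385
328.15,120,504.5074284671
328.15,160,681.1161263051
328.15,200,754.6063778513
328.15,240,801.1719556867
328.15,280,835.7031826468
328.15,320,863.3931549722
328.15,360,886.6462321026
328.15,400,906.7730032443
338.15,120,382.8671439439
338.15,160,592.3866358235
338.15,200,691.7080755995
338.15,240,750.3879763332
338.15,280,791.9201925072
338.15,320,824.2261490791
338.15,360,850.7944938509
338.15,400,873.4453807981
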