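zone,countries,n_birds,core50_km2,homerange95_km2
Alpo-Adriatic,Austria/Italy/Croatia,3,291.37,6803.04
Western Serbia,Serbia,10,190.22,4741.83
Vrachanski Balkan Nature Park,Bulgaria,12,54.17,2249.32
Eastern Balkan Mountains,Bulgaria,9,30.416,1171.38
Struma and Vardar Valleys,Bulgaria/North Macedonia,31,190.36,7578.93
Eastern Rhodopes,Bulgaria/Greece,22,422.63,8371.15
Western Greece,Greece,10,363.54,7242.78
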