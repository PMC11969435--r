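system,quantity,mean,sd
ND^2-25PEG_500-OH,Rg,6.4,0.1
ND^2-50PEG_500-OH,Rg,7.0,0.1
ND^2-100PEG_500-OH,Rg,7.6,0.1
ND^2-50PEG_500-CH3,Rg,7.1,0.1
TiO2^2-50PEG_500-CH3,Rg,6.7,0.1
ND^5-360PEG_500-OH,Rg,7.99,0.02
ND^5-360PEG_1000-OH,Rg,12.40,0.04
ND^2-25PEG_500-OH,h,16,2
ND^2-50PEG_500-OH,h,18,2
ND^2-100PEG_500-OH,h,21,2
ND^2-50PEG_500-CH3,h,19,2
TiO2^2-50PEG_500-CH3,h,17.0,0.5
ND^5-360PEG_500-OH,h,22,2
ND^5-360PEG_1000-OH,h,36,3
ND^2-25PEG_500-OH,d,22,3
ND^2-50PEG_500-OH,d,27,2
ND^2-100PEG_500-OH,d,31,2
ND^2-50PEG_500-CH3,d,28,3
TiO2^2-50PEG_500-CH3,d,27,2
ND^5-360PEG_500-OH,d,46,2
ND^5-360PEG_1000-OH,d,60,3
ND^2-25PEG_500-OH,thk,12.46,0.03
ND^2-50PEG_500-OH,thk,16.48,0.03
ND^2-100PEG_500-OH,thk,20.18,0.03
ND^2-50PEG_500-CH3,thk,16.88,0.03
TiO2^2-50PEG_500-CH3,thk,15.17,0.03
ND^5-360PEG_500-OH,thk,22.03,0.03
ND^5-360PEG_1000-OH,thk,34.84,0.03
ND^2-25PEG_500-OH,E_NP_PEG,-35,14
ND^2-50PEG_500-OH,E_NP_PEG,218,23
ND^2-100PEG_500-OH,E_NP_PEG,449,23
ND^2-50PEG_500-CH3,E_NP_PEG,215,17
TiO2^2-50PEG_500-CH3,E_NP_PEG,-485,11
ND^5-360PEG_500-OH,E_NP_PEG,3363,56
ND^5-360PEG_1000-OH,E_NP_PEG,3346,56
ND^2-25PEG_500-OH,E_PEG_PEG,-1459,27
ND^2-50PEG_500-OH,E_PEG_PEG,-3090,57
ND^2-100PEG_500-OH,E_PEG_PEG,-6042,95
ND^2-50PEG_500-CH3,E_PEG_PEG,-1969,40
TiO2^2-50PEG_500-CH3,E_PEG_PEG,-1262,23
ND^5-360PEG_500-OH,E_PEG_PEG,-24247,156
ND^5-360PEG_1000-OH,E_PEG_PEG,-28589,156
ND^2-25PEG_500-OH,E_NP_water,-37,9
ND^2-50PEG_500-OH,E_NP_water,-3,5
ND^2-100PEG_500-OH,E_NP_water,-5,1
ND^2-50PEG_500-CH3,E_NP_water,0,4
TiO2^2-50PEG_500-CH3,E_NP_water,-420,19
ND^5-360PEG_500-OH,E_NP_water,-26,7
ND^5-360PEG_1000-OH,E_NP_water,5,7
ND^2-25PEG_500-OH,E_PEG_water,-3280,48
ND^2-50PEG_500-OH,E_PEG_water,-6109,117
ND^2-100PEG_500-OH,E_PEG_water,-10782,170
ND^2-50PEG_500-CH3,E_PEG_water,-4609,177
TiO2^2-50PEG_500-CH3,E_PEG_water,-5205,36
ND^5-360PEG_500-OH,E_PEG_water,-33022,240
ND^5-360PEG_1000-OH,E_PEG_water,-74886,335
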