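compound,expected_rt,m1,m2,m3,m4,r2,r3,r4
Ethanol,6.64,31,45,46,29,0.777,0.343,0.249
Acetone,7.37,43,58,42,39,0.262,0.076,0.044
Isopropyl alcohol,7.58,45,41,27,39,0.107,0.090,0.072
Acetonitril,7.90,41,40,39,38,0.546,0.223,0.137
Ethyl acetate,10.59,43,45,70,61,0.137,0.116,0.105
1-butanol,13.38,56,41,43,31,0.720,0.543,0.346
2-pentanone,13.95,43,86,41,71,0.249,0.127,0.109
Pyridine,16.42,79,52,51,50,0.564,0.275,0.205
"1,2-dimethylbenzene",20.39,91,106,77,51,0.327,0.080,0.077
"1,3-dimethylbenzene",20.69,91,106,105,77,0.533,0.223,0.115
"1,4-dimethylbenzene",21.80,91,106,105,77,0.488,0.189,0.109
Benzaldehyde,25.71,106,105,77,51,0.990,0.935,0.404
Indole,38.63,117,90,89,63,0.414,0.313,0.103
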