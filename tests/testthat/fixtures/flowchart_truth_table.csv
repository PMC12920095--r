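tumour_pattern,glands_present,has_transparent_gland,mean_transparency,penetration_um,stratification_visible,expected,indeterminate
1,1,1,85,300,1,IMC,0
1,1,1,85,300,0,IMC,0
1,1,1,85,600,1,IMC,0
1,1,1,85,600,0,IMC,0
1,1,1,60,300,1,IMC,0
1,1,1,60,300,0,IMC,0
1,1,1,60,600,1,IMC,0
1,1,1,60,600,0,IMC,0
1,1,0,85,300,1,IMC,0
1,1,0,85,300,0,IMC,0
1,1,0,85,600,1,IMC,0
1,1,0,85,600,0,IMC,0
1,1,0,60,300,1,IMC,0
1,1,0,60,300,0,IMC,0
1,1,0,60,600,1,IMC,0
1,1,0,60,600,0,IMC,0
1,0,1,85,300,1,IMC,0
1,0,1,85,300,0,IMC,0
1,0,1,85,600,1,IMC,0
1,0,1,85,600,0,IMC,0
1,0,1,60,300,1,IMC,0
1,0,1,60,300,0,IMC,0
1,0,1,60,600,1,IMC,0
1,0,1,60,600,0,IMC,0
1,0,0,85,300,1,IMC,0
1,0,0,85,300,0,IMC,0
1,0,0,85,600,1,IMC,0
1,0,0,85,600,0,IMC,0
1,0,0,60,300,1,IMC,0
1,0,0,60,300,0,IMC,0
1,0,0,60,600,1,IMC,0
1,0,0,60,600,0,IMC,0
0,1,1,85,300,1,D,0
0,1,1,85,300,0,D,0
0,1,1,85,600,1,D,0
0,1,1,85,600,0,D,0
0,1,1,60,300,1,D,0
0,1,1,60,300,0,D,0
0,1,1,60,600,1,D,0
0,1,1,60,600,0,D,0
0,1,0,85,300,1,D,0
0,1,0,85,300,0,D,0
0,1,0,85,600,1,D,0
0,1,0,85,600,0,D,0
0,1,0,60,300,1,IM,0
0,1,0,60,300,0,IM,0
0,1,0,60,600,1,IM,0
0,1,0,60,600,0,IM,0
0,0,1,85,300,1,GM,0
0,0,1,85,300,0,GM,0
0,0,1,85,600,1,NSM,0
0,0,1,85,600,0,NSM,1
0,0,1,60,300,1,GM,0
0,0,1,60,300,0,GM,0
0,0,1,60,600,1,NSM,0
0,0,1,60,600,0,NSM,1
0,0,0,85,300,1,GM,0
0,0,0,85,300,0,GM,0
0,0,0,85,600,1,NSM,0
0,0,0,85,600,0,NSM,1
0,0,0,60,300,1,GM,0
0,0,0,60,300,0,GM,0
0,0,0,60,600,1,NSM,0
0,0,0,60,600,0,NSM,1
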