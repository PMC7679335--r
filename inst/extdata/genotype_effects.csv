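species,WT,G1,G2
SM,0,52,52
Gb3Cer,30,0,0
LacCer,-42,-42,-42
GlcCer,0,-29,-29
Cer,0,-86,-86
GM3,0,0,0
Gb5Cer,0,-34,-34
MSGb5Cer,0,50,50
GM1b,0,0,0
GA1,0,-36,-36
GD1alpha,0,58,58
DSGb5Cer,0,53,53
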