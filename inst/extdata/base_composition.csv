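species,percent
SM,26.3
Gb3Cer,18
LacCer,15.6
GlcCer,12.5
Cer,5.7
GM3,5.2
Gb5Cer,4.9
MSGb5Cer,4.5
GM1b,3.4
GA1,2.4
GD1alpha,1.0
DSGb5Cer,0.4
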