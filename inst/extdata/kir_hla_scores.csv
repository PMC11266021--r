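kir_locus,pattern,class,weight
KIR2DL1,C2,inhibitory,3
KIR2DL2,C1,inhibitory,2
KIR2DL2,C1_C2,inhibitory,2
KIR2DL3,C1,inhibitory,1
KIR3DL1,Bw4-80I,inhibitory,3
KIR3DL1,Bw4-80T,inhibitory,2
KIR3DL2,A3,inhibitory,1
KIR3DL2,A11,inhibitory,1
KIR2DS1,C2,activating,2
KIR2DS2,C1,activating,1
KIR2DS4,A11,activating,1
KIR3DS1,Bw4-80I,activating,2
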