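locus,allele,motif
HLA-A,01:01,none
HLA-A,02:01,none
HLA-A,02:07,none
HLA-A,03:01,A3
HLA-A,03:02,A3
HLA-A,11:01,A11
HLA-A,11:02,A11
HLA-A,23:01,Bw4-80I
HLA-A,24:02,Bw4-80I
HLA-A,25:01,Bw4-80I
HLA-A,26:01,none
HLA-A,29:02,none
HLA-A,30:01,none
HLA-A,31:01,none
HLA-A,32:01,Bw4-80I
HLA-A,33:01,none
HLA-A,68:01,none
HLA-B,07:02,none
HLA-B,08:01,none
HLA-B,13:02,Bw4-80I
HLA-B,14:02,none
HLA-B,15:01,none
HLA-B,18:01,none
HLA-B,27:05,Bw4-80T
HLA-B,35:01,none
HLA-B,37:01,Bw4-80T
HLA-B,38:01,Bw4-80I
HLA-B,39:01,none
HLA-B,40:01,none
HLA-B,44:02,Bw4-80T
HLA-B,44:03,Bw4-80T
HLA-B,46:01,C1
HLA-B,51:01,Bw4-80I
HLA-B,52:01,Bw4-80I
HLA-B,53:01,Bw4-80I
HLA-B,55:01,none
HLA-B,56:01,none
HLA-B,57:01,Bw4-80I
HLA-B,58:01,Bw4-80I
HLA-B,73:01,C1
HLA-C,01:02,C1
HLA-C,02:02,C2
HLA-C,03:02,C1
HLA-C,03:03,C1
HLA-C,03:04,C1
HLA-C,04:01,C2
HLA-C,05:01,C2
HLA-C,06:02,C2
HLA-C,07:01,C1
HLA-C,07:02,C1
HLA-C,07:04,C1
HLA-C,08:01,C1
HLA-C,08:02,C1
HLA-C,12:02,C1
HLA-C,12:03,C1
HLA-C,14:02,C1
HLA-C,15:02,C2
HLA-C,16:01,C1
HLA-C,16:02,C2
HLA-C,17:01,C2
HLA-C,18:01,C2
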