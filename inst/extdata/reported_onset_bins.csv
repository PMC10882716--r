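bin,lo,hi,n
0-30,0,30,734
30-60,30,60,206
60-90,60,90,102
90-120,90,120,57
120-150,120,150,42
150-180,150,180,29
180-360,180,360,118
360+,360,Inf,223
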