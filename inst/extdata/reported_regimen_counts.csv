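regimen,n_psych,n_all
exenatide,3948,72377
liraglutide,1152,28980
lixisenatide,12,311
dulaglutide,1833,52158
semaglutide,1033,17741
tirzepatide,262,9671
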