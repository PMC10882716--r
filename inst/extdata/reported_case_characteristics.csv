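block,level,n
sex,F,5429
sex,M,2551
sex,UNK,260
region,US,7673
region,GB,299
region,JP,137
region,BR,68
region,AU,47
region,ZA,7
region,UNK,9
outcome,DE,79
outcome,LT,43
outcome,HO,883
outcome,DS,111
outcome,CA,1
outcome,RI,14
outcome,OT,1064
outcome,NONE,6045
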