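scorer,PAU,SYB,ASB,MVT,UNK,SIH
EM,1064433,13403481,1569436,3400497,2694942,383191
AUREA,1688600,11966554,2078901,5251091,1530834,0
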