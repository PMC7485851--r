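reference,PAU,SYB,ASB,UNKNOWN
PAU,827708,60918,14198,161609
SYB,258138,11216048,402054,1527241
ASB,69212,42649,1189612,267963
UNKNOWN,533542,646939,473037,4825112
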