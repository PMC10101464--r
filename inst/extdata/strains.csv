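strain,phylotype,group
B,NA,laboratory
C,NA,laboratory
K-12,NA,laboratory
UMB1358,A,UTI
UMB1180,A,UTI
UMB1195,B1,UTI
UMB5924,B1,UTI
UMB1220,B2,UTI
UMB1162,B2,UTI
UMB1225,B2,UTI
UMB1337,B2,UTI
UMB7431,D,UTI
UMB0103,F,OAB
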