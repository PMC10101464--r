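phage,strain,lysis
i527,B,0
i527,C,1
i527,K-12,0
i527,UMB1358,0
i527,UMB1180,0
i527,UMB1195,0
i527,UMB5924,1
i527,UMB1220,1
i527,UMB1162,0
i527,UMB1225,1
i527,UMB1337,0
i527,UMB7431,0
i527,UMB0103,0
i6653,B,1
i6653,C,1
i6653,K-12,1
i6653,UMB1358,0
i6653,UMB1180,0
i6653,UMB1195,0
i6653,UMB5924,1
i6653,UMB1220,0
i6653,UMB1162,0
i6653,UMB1225,1
i6653,UMB1337,0
i6653,UMB7431,0
i6653,UMB0103,0
i6721,B,0
i6721,C,1
i6721,K-12,0
i6721,UMB1358,1
i6721,UMB1180,0
i6721,UMB1195,0
i6721,UMB5924,0
i6721,UMB1220,1
i6721,UMB1162,1
i6721,UMB1225,1
i6721,UMB1337,0
i6721,UMB7431,0
i6721,UMB0103,1
i9006,B,0
i9006,C,1
i9006,K-12,0
i9006,UMB1358,0
i9006,UMB1180,0
i9006,UMB1195,0
i9006,UMB5924,0
i9006,UMB1220,0
i9006,UMB1162,0
i9006,UMB1225,0
i9006,UMB1337,0
i9006,UMB7431,0
i9006,UMB0103,0
i9105,B,0
i9105,C,1
i9105,K-12,0
i9105,UMB1358,0
i9105,UMB1180,0
i9105,UMB1195,0
i9105,UMB5924,0
i9105,UMB1220,0
i9105,UMB1162,0
i9105,UMB1225,1
i9105,UMB1337,0
i9105,UMB7431,0
i9105,UMB0103,0
i9208,B,0
i9208,C,1
i9208,K-12,1
i9208,UMB1358,0
i9208,UMB1180,0
i9208,UMB1195,0
i9208,UMB5924,1
i9208,UMB1220,0
i9208,UMB1162,0
i9208,UMB1225,1
i9208,UMB1337,0
i9208,UMB7431,0
i9208,UMB0103,0
i9344,B,0
i9344,C,1
i9344,K-12,1
i9344,UMB1358,0
i9344,UMB1180,0
i9344,UMB1195,0
i9344,UMB5924,1
i9344,UMB1220,0
i9344,UMB1162,0
i9344,UMB1225,1
i9344,UMB1337,0
i9344,UMB7431,0
i9344,UMB0103,0
i9346,B,0
i9346,C,1
i9346,K-12,0
i9346,UMB1358,0
i9346,UMB1180,0
i9346,UMB1195,0
i9346,UMB5924,0
i9346,UMB1220,0
i9346,UMB1162,0
i9346,UMB1225,1
i9346,UMB1337,0
i9346,UMB7431,0
i9346,UMB0103,0
i9930-1,B,0
i9930-1,C,1
i9930-1,K-12,1
i9930-1,UMB1358,0
i9930-1,UMB1180,0
i9930-1,UMB1195,0
i9930-1,UMB5924,1
i9930-1,UMB1220,0
i9930-1,UMB1162,0
i9930-1,UMB1225,1
i9930-1,UMB1337,0
i9930-1,UMB7431,0
i9930-1,UMB0103,0
i9930-2,B,0
i9930-2,C,1
i9930-2,K-12,1
i9930-2,UMB1358,0
i9930-2,UMB1180,0
i9930-2,UMB1195,0
i9930-2,UMB5924,1
i9930-2,UMB1220,0
i9930-2,UMB1162,0
i9930-2,UMB1225,0
i9930-2,UMB1337,0
i9930-2,UMB7431,0
i9930-2,UMB0103,0
Lust,B,1
Lust,C,1
Lust,K-12,1
Lust,UMB1358,0
Lust,UMB1180,0
Lust,UMB1195,0
Lust,UMB5924,1
Lust,UMB1220,1
Lust,UMB1162,1
Lust,UMB1225,0
Lust,UMB1337,0
Lust,UMB7431,0
Lust,UMB0103,0
Greed,B,1
Greed,C,1
Greed,K-12,1
Greed,UMB1358,0
Greed,UMB1180,0
Greed,UMB1195,0
Greed,UMB5924,1
Greed,UMB1220,1
Greed,UMB1162,1
Greed,UMB1225,0
Greed,UMB1337,0
Greed,UMB7431,1
Greed,UMB0103,0
K30,B,1
K30,C,1
K30,K-12,0
K30,UMB1358,0
K30,UMB1180,0
K30,UMB1195,0
K30,UMB5924,0
K30,UMB1220,1
K30,UMB1162,1
K30,UMB1225,1
K30,UMB1337,0
K30,UMB7431,0
K30,UMB0103,0
P22,B,1
P22,C,0
P22,K-12,0
P22,UMB1358,0
P22,UMB1180,0
P22,UMB1195,1
P22,UMB5924,0
P22,UMB1220,1
P22,UMB1162,0
P22,UMB1225,0
P22,UMB1337,0
P22,UMB7431,1
P22,UMB0103,0
T2,B,1
T2,C,1
T2,K-12,1
T2,UMB1358,1
T2,UMB1180,1
T2,UMB1195,0
T2,UMB5924,1
T2,UMB1220,1
T2,UMB1162,1
T2,UMB1225,1
T2,UMB1337,0
T2,UMB7431,1
T2,UMB0103,1
T3,B,1
T3,C,1
T3,K-12,1
T3,UMB1358,0
T3,UMB1180,0
T3,UMB1195,1
T3,UMB5924,1
T3,UMB1220,1
T3,UMB1162,1
T3,UMB1225,0
T3,UMB1337,0
T3,UMB7431,1
T3,UMB0103,1
T6,B,1
T6,C,1
T6,K-12,1
T6,UMB1358,0
T6,UMB1180,1
T6,UMB1195,1
T6,UMB5924,1
T6,UMB1220,1
T6,UMB1162,1
T6,UMB1225,0
T6,UMB1337,0
T6,UMB7431,1
T6,UMB0103,1
T7,B,1
T7,C,1
T7,K-12,1
T7,UMB1358,0
T7,UMB1180,0
T7,UMB1195,1
T7,UMB5924,1
T7,UMB1220,1
T7,UMB1162,0
T7,UMB1225,0
T7,UMB1337,0
T7,UMB7431,1
T7,UMB0103,0
N4,B,0
N4,C,1
N4,K-12,1
N4,UMB1358,1
N4,UMB1180,1
N4,UMB1195,1
N4,UMB5924,0
N4,UMB1220,1
N4,UMB1162,1
N4,UMB1225,1
N4,UMB1337,1
N4,UMB7431,0
N4,UMB0103,1
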