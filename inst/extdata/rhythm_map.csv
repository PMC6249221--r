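code,rhythm
VF,VF
VFIB,VF
(VF,VF
(VFIB,VF
VT,VT
(VT,VT
VFL,VFL
(VFL,VFL
N,N
(N,N
NSR,N
SR,N
AFIB,N
(AFIB,N
SVTA,N
(SVTA,N
B,N
(B,N
NOISE,noise
(NOISE,noise
ARTIFACT,artifact
ASYS,asystole
(ASYS,asystole
TRANS,transition
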