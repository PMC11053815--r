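# N-end rule half-lives, mammalian reticulocytes in vitro, in hours,
# as reported by ExPASy ProtParam (Bachmair, Finley & Varshavsky 1986 and
# follow-up work). Proline's ">20 h" entry is recorded as 20.
residue,half_life_hours
A,4.4
R,1.0
N,1.4
D,1.1
C,1.2
Q,0.8
E,1.0
G,30.0
H,3.5
I,20.0
L,5.5
K,1.3
M,30.0
F,1.1
P,20.0
S,1.9
T,7.2
W,2.8
Y,2.8
V,100.0
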