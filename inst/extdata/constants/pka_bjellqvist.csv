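# Ionizable-group pKa values, Bjellqvist et al. (1993) Electrophoresis
# 14:1023-1031, the set used by ExPASy ProtParam for isoelectric points.
# group: side chain residue, Nterm/Cterm defaults, or residue-specific termini.
group,kind,pka,charge
K,side,10.0,positive
R,side,12.0,positive
H,side,5.98,positive
D,side,4.05,negative
E,side,4.45,negative
C,side,9.0,negative
Y,side,10.0,negative
Nterm,nterm_default,7.5,positive
A,nterm,7.59,positive
M,nterm,7.0,positive
S,nterm,6.93,positive
P,nterm,8.36,positive
T,nterm,6.82,positive
V,nterm,7.44,positive
E,nterm,7.7,positive
Cterm,cterm_default,3.55,negative
D,cterm,4.55,negative
E,cterm,4.75,negative
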