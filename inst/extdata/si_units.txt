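# SI unit tokens accepted for continuous factor values (case-sensitive).
# Base units first, then lab-relevant prefixed forms of g, m, s, L, mol, M.
m
kg
s
A
K
mol
cd
g
mg
µg
ng
pg
km
cm
mm
µm
nm
ms
µs
ns
L
mL
µL
nL
mmol
µmol
nmol
pmol
M
mM
µM
nM
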