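element	radius
H	1.20
He	1.40
Li	1.82
C	1.70
N	1.55
O	1.52
F	1.47
Ne	1.54
Na	2.27
Mg	1.73
Si	2.10
P	1.80
S	1.80
Cl	1.75
Ar	1.88
K	2.75
Ca	2.31
Mn	2.05
Fe	2.05
Co	2.00
Ni	1.63
Cu	1.40
Zn	1.39
Ga	1.87
As	1.85
Se	1.90
Br	1.85
Kr	2.02
Cd	1.58
I	1.98
Xe	2.16
Hg	1.55
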