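# Single-bond covalent radii, Angstrom, used by the smooth coordination
# number counting function. Source: Pyykko & Atsumi, Chem. Eur. J. 15 (2009)
# 186 (the set adopted by the D3 family of semiclassical dispersion models).
# Columns: element	covalent_radius_A
element	covalent_radius_A
H	0.32
He	0.46
Li	1.33
Be	1.02
B	0.85
C	0.75
N	0.71
O	0.63
F	0.64
Ne	0.67
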