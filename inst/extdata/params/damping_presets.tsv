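# Becke-Johnson rational-damping parameters per density functional, for the
# coordination-number-dependent engine. s6 and s8 are dimensionless global
# scalings; a1 is dimensionless; a2 is in bohr. Source: the published BJ
# damping parameterizations of the D3 model (Grimme, Ehrlich & Goerigk,
# J. Comput. Chem. 32, 1456, 2011).
# Columns: preset	s6	s8	a1	a2_bohr
preset	s6	s8	a1	a2_bohr
pbe0	1.0000	1.2177	0.4145	4.8593
b3lyp	1.0000	1.9889	0.3981	4.4211
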