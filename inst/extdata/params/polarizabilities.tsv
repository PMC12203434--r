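# Static dipole polarizabilities, cubic Angstrom.
# Neutral atoms: 2018 recommended values (Schwerdtfeger & Nagle,
# Mol. Phys. 117, 1200), converted from atomic units (1 au = 0.1481847 A^3).
# Li: experimental atom-interferometry value (Miffre et al. 2006), 24.33 A^3.
# Li+: spectroscopic/ab initio closed-shell cation value, 0.0285 A^3.
# Species column: bare element symbol = neutral atom; "+" suffix = monocation.
# Columns: species	polarizability_A3
species	polarizability_A3
H	0.6669
He	0.2050
Li	24.33
Li+	0.0285
Be	5.588
B	3.038
C	1.674
N	1.096
O	0.785
F	0.554
Ne	0.3943
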