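# First ionization energies, eV. For cations ("+" suffix) the value is the
# ionization energy of that species (i.e. the second ionization energy of
# the parent element). Source: NIST Atomic Spectra Database, ground-state
# ionization energies.
# Columns: species	ionization_eV
species	ionization_eV
H	13.5984
He	24.5874
Li	5.3917
Li+	75.6400
Be	9.3227
B	8.2980
C	11.2603
N	14.5341
O	13.6181
F	17.4228
Ne	21.5645
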