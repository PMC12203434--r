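# Standard atomic weights, amu (unified atomic mass units).
# Source: IUPAC Commission on Isotopic Abundances and Atomic Weights,
# "Standard atomic weights of the elements 2021" (abridged to five
# significant figures; conventional value for intervals).
# Columns: element	atomic_number	mass_amu
element	atomic_number	mass_amu
H	1	1.008
He	2	4.0026
Li	3	6.94
Be	4	9.0122
B	5	10.81
C	6	12.011
N	7	14.007
O	8	15.999
F	9	18.998
Ne	10	20.180
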