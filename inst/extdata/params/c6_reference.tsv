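# Homoatomic C6 dispersion coefficients (hartree bohr^6) tabulated against
# reference coordination numbers, for the coordination-number interpolation
# of environment-dependent C6. Adapted reference data at the magnitudes of
# the published TD-DFT reference sets of the D3-type semiclassical models
# (Grimme et al. 2010); pair coefficients are built from these homoatomic
# values by geometric combination.
# Columns: element	cn_ref	c6_ref_au
element	cn_ref	c6_ref_au
H	0.000	7.59
H	0.912	3.03
He	0.000	1.56
Li	0.000	1163.44
Li	0.980	85.06
Be	0.000	257.49
Be	0.975	55.16
B	0.000	107.18
B	0.971	49.84
B	1.943	28.98
C	0.000	49.11
C	0.987	43.25
C	1.998	29.36
C	2.999	25.78
C	3.984	18.21
N	0.000	25.27
N	0.994	19.68
N	2.014	15.58
N	2.990	12.47
O	0.000	15.51
O	0.993	12.57
O	1.989	10.37
F	0.000	9.69
F	0.998	7.13
Ne	0.000	6.29
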