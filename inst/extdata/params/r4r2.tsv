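# Expectation-value ratios <r^4>/<r^2> (atomic units) used to build C8 from
# C6 via C8_AB = 3 C6_AB sqrt(Q_A Q_B), Q_A = 0.5 sqrt(Z_A) <r4>/<r2>_A.
# Source: the published multipole-expectation set of the D3 dispersion
# correction (Grimme et al., J. Chem. Phys. 132, 154104, 2010).
# Columns: element	r4r2
element	r4r2
H	8.0589
He	3.4698
Li	29.0974
Be	14.8517
B	11.8799
C	7.8715
N	5.5588
O	4.7566
F	3.8025
Ne	3.1036
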