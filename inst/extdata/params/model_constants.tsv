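# Dimensionless constants of the coordination-number machinery.
# cn_k1: steepness of the logistic counting function.
# cn_k2: covalent-radius scaling inside the counting function.
# cn_k3: width of the Gaussian weights in the C6(CN) interpolation.
# cn_cutoff_A: neighbour cutoff (Angstrom) beyond which the counting
#   function is taken as exactly zero; needed because the logistic has a
#   constant floor 1/(1+e^k1) at infinite separation.  The D3 reference
#   implementation applies the same kind of coordination-number cutoff.
# Source: the constants of the D3 model (Grimme et al. 2010).
# Columns: name	value
name	value
cn_k1	16.0
cn_k2	1.3333333333333333
cn_k3	4.0
cn_cutoff_A	20.0
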