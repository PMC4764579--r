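# Reported mole-fraction partition coefficients (Kx), saturating
# relative fluorescence (F/F0max) and partitioning free energies
# (dG, kcal/mol) for DkTx and its constructs.
# NOTE: the K2K2 Kx exponent is reported inconsistently at source
# (8.1e4 in one place, 8.1e5 in another); 8.1e4 is the value consistent
# with the reported dG = -6.6 kcal/mol at 293 K and is the one used here.
construct,k_x,k_x_se,f_max,f_max_se,dg_printed
DkTx,2.3e6,0.7e6,2.65,0.08,-8.5
K1,3.9e5,1.1e5,2.63,0.07,-7.5
K2,2.0e4,0.3e4,3.71,0.40,-5.8
K1K1,2.9e6,0.3e6,2.47,0.03,-8.7
K2K2,8.1e4,2.0e4,2.77,0.55,-6.6
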