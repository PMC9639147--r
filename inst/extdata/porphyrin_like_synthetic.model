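# Synthetic porphyrin-like two-mode chromophore (not ab initio data):
# 2.28 eV gap, two displaced skeletal modes, in-plane transition dipole
# with weak Herzberg-Teller derivatives.
[electronic]
gap_eV 2.28
[modes]
# k freq_g_cm1 freq_e_cm1 displacement
1 800 800 0.2
2 1400 1400 0.244948974968282
[dipole]
mu0 0.8 0.5 0.2
dmu 1 0.03 0.02 0.01
dmu 2 0.01 0.04 0.02
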