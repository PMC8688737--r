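# dipolar hard tetrahedra, strong dipole, screened at short range
model = ht
eta = 0.425
lambda = 1
dipole_mode = screened
l0 = 0.001
n = 512
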