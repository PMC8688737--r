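# primitive model, lambda = 7, full dipole-dipole interaction
model = pm
eta = 0.35
beta_eps = 8
lambda = 7
dipole_mode = full
l0 = 0.01
n = 512
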