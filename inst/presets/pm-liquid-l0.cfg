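# primitive model, no dipole: published state point
model = pm
eta = 0.35
beta_eps = 8
dipole_mode = none
n = 512
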