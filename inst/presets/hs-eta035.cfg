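# hard-sphere comparison fluid at liquid packing
model = hs
eta = 0.35
n = 512
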