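# hard tetrahedra near the onset of metastability
model = ht
eta = 0.425
n = 512
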